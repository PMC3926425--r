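# End-to-end orchestration: train a texture model from annotated images;
# refine a rough user contour into a labeled, measured region.

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its default. The defaults for
#' the snake (`alpha = 1.44`, `beta = 1.58`, `search_radius = 8`), the field
#' weights (`delta1 = 0.6` for the gradient term, `delta2 = 0.99` for the
#' texture-classification term), the gradient scale (`sigma = 23` px), the
#' block size (37 px) and the classifier cost (`c = 1.5`, linear kernel) are
#' the operating settings for full-resolution biopsy micrographs; `sigma`
#' in particular must be chosen relative to the object scale (see
#' [phantom_config()] for the benchmark-scale variant).
#'
#' @param block_size texture block side, px.
#' @param kernel a [kernel_spec()].
#' @param cost classifier cost parameter.
#' @param snake a [snake_params()].
#' @param delta1 weight of the gradient edge term f1.
#' @param delta2 weight of the texture-classification edge term f2.
#' @param sigma Gaussian scale of f1, px.
#' @param eta decay of the annotation-distance modulation, per px.
#' @param erosion_radius erosion disk radius of the annotation term, px.
#' @param smooth_sigma,thresh_window,thresh_offset,canny_sigma,canny_quantiles,capture_sigma
#'   f2 postprocessing settings, see [edge_term_f2()]. The default
#'   `thresh_offset` of 0.25 places the binarization threshold near the
#'   half-level between the background and foreground greylevels of the
#'   class image: with isolated objects the local mean sits close to the
#'   background level, and thresholding at the bare local mean would keep
#'   the whole smoothed skirt of a region, biasing its outline outward.
#' @param majority_window,majority_passes majority-vote smoothing settings;
#'   the default is a single pass, because iterating the strict-majority
#'   rule acts as a morphological erosion on compact label blobs and can
#'   shrink genuine regions only a few cells across to nothing.
#' @param levels co-occurrence quantization levels.
#' @param classify_stride grid step of the inference-time block
#'   classification used to build the f2 term and label regions; the
#'   default `block_size %/% 4` oversamples the label map relative to the
#'   plain tiling, so that the majority-vote denoising does not swallow
#'   regions only a couple of blocks across and the classified region
#'   outline tracks the true boundary to a few pixels.
#' @param train_stride block-sampling stride used at training time (much
#'   denser than the inference tiling, because a region barely larger than
#'   the block admits only a few fully-inside block origins); default
#'   `max(3, block_size %/% 9)`.
#' @param max_blocks_per_class cap on training blocks per class per image.
#' @param cal optional [calibration()].
#' @return an object of class `textsnake_config`.
#' @export
textsnake_config <- function(block_size = 37L,
                             kernel = kernel_spec("linear"),
                             cost = 1.5,
                             snake = snake_params(),
                             delta1 = 0.6, delta2 = 0.99,
                             sigma = 23, eta = 0.05,
                             erosion_radius = 3L,
                             smooth_sigma = 2, thresh_window = 151,
                             thresh_offset = 0.25,
                             canny_sigma = 1,
                             canny_quantiles = c(0.70, 0.90),
                             capture_sigma = 6,
                             majority_window = 3L, majority_passes = 1L,
                             levels = 32L,
                             classify_stride = NULL,
                             train_stride = NULL,
                             max_blocks_per_class = 60L,
                             cal = NULL) {
  if (delta1 < 0 || delta2 < 0) stop("delta weights must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(
    block_size = as.integer(block_size), kernel = kernel, cost = cost,
    snake = snake, delta1 = delta1, delta2 = delta2, sigma = sigma,
    eta = eta, erosion_radius = erosion_radius,
    smooth_sigma = smooth_sigma, thresh_window = thresh_window,
    thresh_offset = thresh_offset,
    canny_sigma = canny_sigma, canny_quantiles = canny_quantiles,
    capture_sigma = capture_sigma,
    majority_window = as.integer(majority_window),
    majority_passes = as.integer(majority_passes),
    levels = as.integer(levels),
    classify_stride = as.integer(classify_stride %||% max(1, block_size %/% 4)),
    train_stride = as.integer(train_stride %||% max(3, block_size %/% 9)),
    max_blocks_per_class = as.integer(max_blocks_per_class),
    cal = cal), class = "textsnake_config")
}

#' Benchmark-scale configuration for the synthetic phantoms
#'
#' Identical to [textsnake_config()] except that the gradient scale is
#' `sigma = 3` px: the phantom objects have 25-50 px semi-axes, and a
#' smoothing scale comparable to the object radius would displace the
#' gradient ridge off the boundary (by roughly `sigma^2 / (2 R)` px for a
#' disk of radius R), destroying boundary localization for every method.
#' The full-resolution default of 23 px corresponds to micrographs an order
#' of magnitude larger.
#'
#' @param ... overrides forwarded to [textsnake_config()].
#' @return a `textsnake_config`.
#' @export
phantom_config <- function(...) {
  textsnake_config(sigma = 3, ...)
}

# Training-block harvest for one annotated image: every block on the
# stride grid is labeled by majority coverage — the class of the polygon
# covering at least half of the block, or "background" when no polygon
# does. Including the partially covered boundary blocks (instead of only
# pure fully-inside/fully-outside ones) anchors the classifier's
# foreground/background transition at 50% coverage, so the classified
# region outline tracks the true boundary instead of bulging outward by up
# to half a block.
harvest_blocks <- function(image, annotations, config) {
  px <- as_pixels(image)
  shp <- dim(px)
  bs <- config$block_size
  masks <- lapply(annotations, function(a) contour_to_mask(a$polygon, shp))
  union_mask <- Reduce(`|`, masks, matrix(FALSE, shp[1], shp[2]))
  # integral image for O(1) block sums
  block_sum <- function(mask) {
    S <- apply(apply(mask, 2, cumsum), 1, cumsum)  # S[c, r] after second apply
    S <- t(S)
    Sp <- matrix(0, shp[1] + 1, shp[2] + 1)
    Sp[-1, -1] <- S
    function(r, cc) {
      r2 <- r + bs - 1L; c2 <- cc + bs - 1L
      Sp[r2 + 1, c2 + 1] - Sp[r, c2 + 1] - Sp[r2 + 1, cc] + Sp[r, cc]
    }
  }
  sums <- lapply(masks, block_sum)
  usum <- block_sum(union_mask)
  rows <- seq.int(1L, shp[1] - bs + 1L, by = config$train_stride)
  cols <- seq.int(1L, shp[2] - bs + 1L, by = config$train_stride)
  out_feat <- list(); out_lab <- character(0)
  per_class <- list()
  half <- bs * bs / 2
  for (r in rows) for (cc in cols) {
    cov <- vapply(sums, function(f) f(r, cc), numeric(1))
    lab <- if (usum(r, cc) < half) "background"
           else annotations[[which.max(cov)]]$label
    per_class[[lab]] <- c(per_class[[lab]], list(c(r, cc)))
  }
  # cap per class with an evenly spaced deterministic selection
  for (lab in names(per_class)) {
    origins <- per_class[[lab]]
    if (length(origins) > config$max_blocks_per_class) {
      sel <- unique(round(seq(1, length(origins),
                              length.out = config$max_blocks_per_class)))
      origins <- origins[sel]
    }
    for (o in origins) {
      blk <- px[o[1]:(o[1] + bs - 1L), o[2]:(o[2] + bs - 1L)]
      out_feat <- c(out_feat, list(extract_features(blk, levels = config$levels)))
      out_lab <- c(out_lab, lab)
    }
  }
  list(features = do.call(rbind, out_feat), labels = out_lab)
}

#' Train the texture classification model from annotated images
#'
#' Harvests square blocks from each training image on a dense stride grid;
#' each block is labeled by majority coverage: the class of the polygon
#' covering at least half of it, or an implicit `"background"` class when
#' no polygon does (so partially covered boundary blocks teach the
#' classifier where the region outline lies). Features are z-scored with
#' training-set statistics (stored in the model) and a one-vs-one
#' maximum-margin model is trained.
#'
#' @param training list of training items, each a list with `image` (a
#'   [gray_image()]) and `annotations` (list of [annotation_record()]s).
#' @param config a [textsnake_config()].
#' @return a `maxmargin_multiclass` model with a `training_log` attribute
#'   recording per-class sample counts.
#' @export
train_model <- function(training, config = textsnake_config()) {
  harvests <- lapply(training, function(item)
    harvest_blocks(item$image, item$annotations, config))
  X <- do.call(rbind, lapply(harvests, `[[`, "features"))
  y <- unlist(lapply(harvests, `[[`, "labels"))
  wanted <- unique(unlist(lapply(training, function(item)
    vapply(item$annotations, `[[`, character(1), "label"))))
  missing <- setdiff(wanted, unique(y))
  if (length(missing))
    stop("no training block is majority-covered by any polygon of class: ",
         paste(missing, collapse = ", "))
  model <- train_multiclass(X, y, spec = config$kernel, cost = config$cost,
                            scale = TRUE)
  attr(model, "training_log") <- table(y)
  model
}

# Internal: the supervised force field of an image given a model and an
# initial contour. Returns the field plus the filtered block label map.
build_field <- function(image, initial, model, config, supervised = TRUE,
                        label_map = NULL) {
  px <- as_pixels(image)
  f1 <- edge_term_f1(px, sigma = config$sigma)
  terms <- list(f1); delta <- config$delta1
  if (supervised) {
    if (is.null(label_map))
      label_map <- classify_blocks(px, model, block_size = config$block_size,
                                   stride = config$classify_stride,
                                   levels = config$levels)
    label_map <- majority_filter(label_map, window = config$majority_window,
                                 max_passes = config$majority_passes)
    # Binary rendering for the edge term: all foreground classes share one
    # greylevel, so the only edges the f2 pipeline can produce lie on the
    # classified foreground/background outline. A class-coded rendering
    # (default_greylevels) would add spurious edges at transitions between
    # the region interior and mislabeled boundary-straddling blocks.
    grey <- stats::setNames(rep(255, length(model$class_names)),
                            model$class_names)
    grey["background"] <- 0
    class_img <- label_map_to_image(label_map, grey)
    f2 <- edge_term_f2(class_img, smooth_sigma = config$smooth_sigma,
                       thresh_window = config$thresh_window,
                       thresh_offset = config$thresh_offset,
                       canny_sigma = config$canny_sigma,
                       canny_quantiles = config$canny_quantiles,
                       capture_sigma = config$capture_sigma)
    terms <- c(terms, list(f2)); delta <- c(delta, config$delta2)
  }
  T <- annotation_term(initial, dim(px), erosion_radius = config$erosion_radius)
  field <- compose_external_energy(terms, delta, T = T, eta = config$eta)
  list(field = field, label_map = label_map)
}

finish_region <- function(image, contour, label, config) {
  mask <- contour_to_mask(contour, dim(as_pixels(image)))
  a <- area(mask, config$cal)
  structure(list(contour = contour, mask = mask, label = label,
                 area_px = a$pixels, area_um2 = a$physical,
                 omega_vs_truth = NULL,
                 failed = a$pixels == 0),
            class = "annotated_region")
}

#' Supervised segmentation and annotation of one region
#'
#' Composes the full force field (gradient term, texture-classification
#' term, annotation-distance modulation from the initial contour), evolves
#' the snake from the initial contour, and labels the final region by the
#' majority class of the classified blocks whose centers fall inside the
#' final mask (ties broken by the largest mean absolute decision margin,
#' then lexicographically).
#'
#' @param image a [gray_image()].
#' @param initial rough initial contour, n x 2 (row, col) matrix.
#' @param model a trained model from [train_model()].
#' @param config a [textsnake_config()].
#' @param label_map optional raw block classification of this image from
#'   [classify_blocks()] (before majority filtering), to be reused when
#'   several regions of the same image are segmented; computed internally
#'   when `NULL`.
#' @return an `annotated_region`: list with `contour`, `mask`, `label`,
#'   `area_px`, `area_um2`, and `failed` (`TRUE` when the final mask is
#'   empty).
#' @export
segment_supervised <- function(image, initial, model,
                               config = textsnake_config(),
                               label_map = NULL) {
  bf <- build_field(image, initial, model, config, supervised = TRUE,
                    label_map = label_map)
  final <- evolve(initial, bf$field, config$snake)
  region <- finish_region(image, final, NA_character_, config)
  if (!region$failed) {
    region$label <- region_label(bf$label_map, region$mask)
  }
  region
}

# Majority label over the classified blocks of the final region. Blocks
# entirely contained in the mask carry pure region texture and vote first;
# blocks that merely have their center inside straddle the boundary (mixed
# texture, unreliable label) and are used only when no block lies fully
# inside.
region_label <- function(label_map, mask) {
  bs <- label_map$block_size
  st <- label_map$stride %||% bs
  gr <- nrow(label_map$labels); gc <- ncol(label_map$labels)
  or_r <- (seq_len(gr) - 1L) * st
  or_c <- (seq_len(gc) - 1L) * st
  S <- apply(apply(mask, 2, cumsum), 1, cumsum)
  Sp <- matrix(0, nrow(mask) + 1, ncol(mask) + 1)
  Sp[-1, -1] <- t(S)
  block_cov <- outer(or_r, or_c, function(r, cc)
    Sp[cbind(r + bs + 1, cc + bs + 1)] - Sp[cbind(r + 1, cc + bs + 1)] -
      Sp[cbind(r + bs + 1, cc + 1)] + Sp[cbind(r + 1, cc + 1)])
  full <- block_cov == bs * bs
  ctr_r <- or_r + (bs + 1L) %/% 2L
  ctr_c <- or_c + (bs + 1L) %/% 2L
  center_in <- outer(ctr_r, ctr_c, function(r, cc) mask[cbind(r, cc)])
  inside <- if (any(full)) full else center_in
  if (!any(inside)) return(NA_character_)
  labs <- label_map$labels[inside]
  tab <- table(labs)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  mm <- vapply(top, function(l)
    mean(label_map$margin[inside][labs == l]), numeric(1))
  top <- top[mm == max(mm)]
  sort(top)[1]
}

#' Unsupervised segmentation of one region
#'
#' The classic variant: only the gradient edge term drives the snake (the
#' texture-classification term is forced off regardless of the configured
#' `delta2`); no class label is assigned.
#'
#' @inheritParams segment_supervised
#' @return an `annotated_region` with `label = NA`.
#' @export
segment_unsupervised <- function(image, initial, config = textsnake_config()) {
  bf <- build_field(image, initial, model = NULL, config, supervised = FALSE)
  final <- evolve(initial, bf$field, config$snake)
  finish_region(image, final, NA_character_, config)
}

#' Block-based segmentation mask
#'
#' The union of the blocks classified as `target_label` (after
#' majority-vote smoothing), as a pixel mask. This is the raw classification
#' footprint that the force-field term f2 is derived from; it is coarse by
#' construction (axis-aligned 37 px blocks).
#'
#' @param image a [gray_image()].
#' @param model a trained model.
#' @param config a [textsnake_config()].
#' @param target_label class whose blocks form the mask; `NULL` selects all
#'   non-background classes.
#' @param label_map optional raw block classification to reuse, as in
#'   [segment_supervised()].
#' @return logical mask matrix.
#' @export
block_segmentation_mask <- function(image, model, config = textsnake_config(),
                                    target_label = NULL, label_map = NULL) {
  if (is.null(label_map))
    label_map <- classify_blocks(as_pixels(image), model,
                                 block_size = config$block_size,
                                 stride = config$classify_stride,
                                 levels = config$levels)
  label_map <- majority_filter(label_map, window = config$majority_window,
                               max_passes = config$majority_passes)
  hit <- if (is.null(target_label)) label_map$labels != "background"
         else label_map$labels == target_label
  n <- label_map$image_shape[1]; m <- label_map$image_shape[2]
  ridx <- grid_index(n, nrow(hit), label_map$block_size, label_map$stride)
  cidx <- grid_index(m, ncol(hit), label_map$block_size, label_map$stride)
  hit[ridx, cidx, drop = FALSE]
}
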