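# Synthetic phantom generator.
#
# Phantoms emulate the geometry and texture contrast of stained kidney
# biopsy micrographs at benchmark scale: compact elliptical regions
# (glomerulus-like), elongated tube-like regions (tubule-like), a textured
# background, and small high-contrast clutter blobs standing in for
# interstitial debris. Region textures are stationary Gaussian noise fields
# with class-specific mean and standard deviation, optionally overlaid with
# an oriented sinusoidal grating, which is the minimal structure that
# exercises all seven texture features (mean/std separate intensity levels
# and noise amplitudes; the co-occurrence terms separate gratings).

#' Default phantom texture classes
#'
#' Four foreground classes (two compact "glomerulus"-like, two elongated
#' "tubule"-like) plus the background texture.
#'
#' @return named list of texture parameter lists
#'   (`mean`, `sd`, `grating_period`, `grating_contrast`).
#' @export
phantom_classes <- function() {
  # Every foreground class carries a second-order signature (noise
  # amplitude or a fine grating that survives co-occurrence statistics but
  # is erased by the gradient term's Gaussian smoothing), so regions remain
  # classifiable even where their mean level matches the background.
  # Mean offsets from the background are small (comparable to a few noise
  # standard deviations), emulating weakly stained structures whose edges
  # are faint; class identity is carried mostly by the second-order
  # statistics.
  list(
    background = list(mean = 200, sd = 8,
                      grating_period = NA, grating_contrast = 0),
    glomerulus_normal = list(mean = 188, sd = 10,
                             grating_period = 5, grating_contrast = 15),
    glomerulus_pathogenic = list(mean = 194, sd = 24,
                                 grating_period = 4, grating_contrast = 18),
    tubulus_normal = list(mean = 186, sd = 8,
                          grating_period = 6, grating_contrast = 25),
    tubulus_pathogenic = list(mean = 191, sd = 10,
                              grating_period = 8, grating_contrast = 30)
  )
}

# Ellipse polygon: center (row, col), semi-axes (a_row, a_col), rotation in
# radians, n vertices.
ellipse_polygon <- function(center, semi_axes, angle = 0, n = 72L) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  r0 <- semi_axes[1] * cos(t); c0 <- semi_axes[2] * sin(t)
  cbind(center[1] + r0 * cos(angle) - c0 * sin(angle),
        center[2] + r0 * sin(angle) + c0 * cos(angle))
}

#' Specify a synthetic phantom
#'
#' @param image_shape `(n_rows, n_cols)`, default 300 x 300.
#' @param regions list of region specs; each a list with `shape`
#'   (`"ellipse"` or `"tube"`), `class` (a name from `classes`), `center`
#'   (row, col), `semi_axes` (a, b in px; tubes are strongly elongated
#'   ellipses), and optional `angle` (radians).
#' @param classes texture class parameters, see [phantom_classes()].
#' @param clutter list with `n` (number of background blobs), `radius`
#'   (range, px) and `delta` (intensity offset range); clutter blobs are
#'   preferentially placed near region boundaries.
#' @param fade_arcs if `TRUE` (default), the background mean near a random
#'   angular sector of each region boundary is pulled to the region mean,
#'   producing a faint-boundary arc that gradient edges cannot see.
#' @param seed RNG seed making the phantom deterministic.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(300L, 300L), regions,
                         classes = phantom_classes(),
                         clutter = list(n = 75, radius = c(3, 8),
                                        delta = c(40, 80)),
                         fade_arcs = TRUE,
                         seed = 1L) {
  for (rg in regions) {
    if (!rg$class %in% names(classes))
      stop("unknown region class: ", rg$class)
    if (rg$class == "background") stop("regions cannot use the background class")
  }
  structure(list(image_shape = as.integer(image_shape), regions = regions,
                 classes = classes, clutter = clutter,
                 fade_arcs = isTRUE(fade_arcs), seed = as.integer(seed)),
            class = "phantom_spec")
}

region_polygon <- function(rg) {
  ax <- rg$semi_axes
  ellipse_polygon(rg$center, ax, rg$angle %||% 0)
}

texture_field <- function(shape, params) {
  base <- matrix(params$mean + stats::rnorm(prod(shape), 0, params$sd),
                 shape[1], shape[2])
  if (!is.na(params$grating_period) && params$grating_contrast > 0) {
    ang <- params$grating_angle %||% (pi / 5)
    rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    phase <- 2 * pi * (cos(ang) * cc + sin(ang) * rr) / params$grating_period
    base <- base + params$grating_contrast * sin(phase)
  }
  base
}

#' Generate a phantom image with ground-truth annotations
#'
#' Deterministic given the spec's seed. Region interiors are filled with
#' their class texture, the rest with the background texture plus clutter
#' blobs. Regions must not overlap.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [gray_image()]), `annotations` (list of
#'   [annotation_record()]s with the ground-truth polygons), and `masks`
#'   (list of logical ground-truth masks, one per region).
#' @export
generate_phantom <- function(spec) {
  shp <- spec$image_shape
  with_seed(spec$seed, {
    masks <- list(); polys <- list()
    union_mask <- matrix(FALSE, shp[1], shp[2])
    for (i in seq_along(spec$regions)) {
      rg <- spec$regions[[i]]
      poly <- region_polygon(rg)
      if (any(poly < 1) || any(poly[, 1] > shp[1]) || any(poly[, 2] > shp[2]))
        stop("region ", i, " exceeds the image bounds")
      mask <- contour_to_mask(poly, shp)
      if (any(mask & union_mask))
        stop("region ", i, " overlaps a previous region")
      union_mask <- union_mask | mask
      masks[[i]] <- mask
      polys[[i]] <- poly
    }
    # faded boundary arcs: along a random angular sector of each region the
    # nearby background matches the region's first-order statistics (mean
    # AND noise amplitude), so the local step-edge contrast vanishes and
    # only the region's grating, which the gradient term's Gaussian
    # smoothing erases but co-occurrence statistics retain, separates
    # region from background. This emulates the faint, partially stained
    # boundaries that motivate texture supervision.
    bg <- spec$classes$background
    mean_map <- matrix(bg$mean, shp[1], shp[2])
    sd_map <- matrix(bg$sd, shp[1], shp[2])
    if (isTRUE(spec$fade_arcs) && any(union_mask)) {
      rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
      cc <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
      for (i in seq_along(spec$regions)) {
        rg <- spec$regions[[i]]
        cls <- spec$classes[[rg$class]]
        d_out <- distance_to_mask(masks[[i]])
        theta0 <- stats::runif(1, -pi, pi)
        half <- stats::runif(1, 0.8, 1.2)  # arc half-width, radians
        ang <- atan2(cc - rg$center[2], rr - rg$center[1])
        dang <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
        w <- exp(-d_out^2 / (2 * 14^2)) * exp(-(dang / half)^2)
        mean_map <- mean_map + (cls$mean - bg$mean) * w
        sd_map <- sd_map + (cls$sd - bg$sd) * w
      }
    }
    img <- mean_map + matrix(stats::rnorm(prod(shp)), shp[1], shp[2]) * sd_map
    for (i in seq_along(spec$regions)) {
      rg <- spec$regions[[i]]
      tex <- texture_field(shp, spec$classes[[rg$class]])
      img[masks[[i]]] <- tex[masks[[i]]]
    }
    # clutter blobs in the background, biased towards region boundaries
    cl <- spec$clutter
    if (!is.null(cl) && cl$n > 0) {
      near_band <- if (any(union_mask)) {
        d <- distance_to_mask(union_mask)
        which(d > 3 & d < 30, arr.ind = TRUE)
      } else NULL
      anywhere <- which(!union_mask, arr.ind = TRUE)
      rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
      cc <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
      for (k in seq_len(cl$n)) {
        pool <- if (!is.null(near_band) && nrow(near_band) > 0 &&
                    stats::runif(1) < 0.7) near_band else anywhere
        ctr <- pool[sample.int(nrow(pool), 1L), ]
        rad <- stats::runif(1, cl$radius[1], cl$radius[2])
        dlt <- sample(c(-1, 1), 1) * stats::runif(1, cl$delta[1], cl$delta[2])
        blob <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2
        blob <- blob & !union_mask
        img[blob] <- img[blob] + dlt
      }
    }
    img <- pmin(pmax(round(img), 0), 255)
    anns <- lapply(seq_along(spec$regions), function(i)
      annotation_record(polys[[i]], spec$regions[[i]]$class,
                        image_id = paste0("phantom-", spec$seed)))
    list(image = gray_image(img), annotations = anns, masks = masks)
  })
}

#' Built-in phantom presets
#'
#' The `"biopsy"` preset emulates a 300 x 300 crop of a biopsy micrograph:
#' 2-4 non-overlapping regions drawn from the four foreground classes
#' (compact regions with 26-42 px semi-axes, elongated tubes), textured
#' background, and clutter blobs. Region layout is drawn deterministically
#' from `seed`.
#'
#' @param preset preset name (only `"biopsy"`).
#' @param seed RNG seed.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(preset = "biopsy", seed = 1L) {
  if (!identical(preset, "biopsy")) stop("unknown preset: ", preset)
  with_seed(mix_seed(seed, 13), {
    shp <- c(300L, 300L)
    n_regions <- sample(2:4, 1)
    classes <- sample(c("glomerulus_normal", "glomerulus_pathogenic",
                        "tubulus_normal", "tubulus_pathogenic"),
                      n_regions, replace = n_regions > 4)
    # place regions on a jittered 2 x 2 layout so they cannot overlap
    anchors <- list(c(80, 80), c(80, 220), c(220, 80), c(220, 220))
    anchors <- anchors[sample.int(4, n_regions)]
    regions <- lapply(seq_len(n_regions), function(i) {
      cls <- classes[i]
      ctr <- anchors[[i]] + round(stats::runif(2, -12, 12))
      if (grepl("tubulus", cls)) {
        list(shape = "tube", class = cls, center = ctr,
             semi_axes = c(stats::runif(1, 46, 52), stats::runif(1, 26, 30)),
             angle = stats::runif(1, 0, pi))
      } else {
        list(shape = "ellipse", class = cls, center = ctr,
             semi_axes = sort(stats::runif(2, 28, 42), decreasing = TRUE),
             angle = stats::runif(1, 0, pi))
      }
    })
    phantom_spec(image_shape = shp, regions = regions, seed = seed)
  })
}

#' Rough initial contour emulating a quick user drag
#'
#' Takes the ground-truth mask boundary, pushes each vertex outward along
#' the radial direction by `dilation` pixels, perturbs both coordinates with
#' uniform jitter, smooths with a circular moving average, and resamples.
#' With the defaults the resulting overlap against the truth mask falls in
#' roughly 0.6-0.85 for typical phantom region sizes, emulating a quick,
#' imprecise outline that encloses the object.
#'
#' @param truth_mask logical ground-truth mask (nonempty).
#' @param jitter vertex perturbation half-range, px.
#' @param dilation outward offset, px.
#' @param seed RNG seed (deterministic contour per seed).
#' @return n x 2 contour matrix, clamped to the image bounds.
#' @export
rough_contour <- function(truth_mask, jitter = 3, dilation = 8, seed = 1L) {
  bnd <- mask_to_contour(truth_mask)
  ctr <- colMeans(bnd)
  with_seed(mix_seed(seed, 7), {
    v <- sweep(bnd, 2, ctr)
    len <- pmax(sqrt(rowSums(v^2)), 1e-9)
    # +0.5: the traced boundary runs through pixel centers, half a pixel
    # inside the shape's true extent
    out <- bnd + v / len * (dilation + 0.5)
    out <- out + matrix(stats::runif(length(out), -jitter, jitter),
                        nrow(out), 2)
    # circular moving average to keep the outline smooth
    k <- 7L
    sm <- apply(out, 2, function(x) {
      xx <- c(tail(x, k), x, head(x, k))
      stats::filter(xx, rep(1 / (2 * k + 1), 2 * k + 1))[(k + 1):(k + length(x))]
    })
    sm[, 1] <- pmin(pmax(sm[, 1], 2), nrow(truth_mask) - 1)
    sm[, 2] <- pmin(pmax(sm[, 2], 2), ncol(truth_mask) - 1)
    resample_contour(sm, 5)
  })
}

#' Texture class separation diagnostic
#'
#' Draws pure texture patches for each class, extracts features, and
#' compares the between-class centroid distances with the within-class
#' spread (mean distance to the class centroid), using z-scored features.
#'
#' @param classes texture classes, see [phantom_classes()].
#' @param patch_size patch side, px.
#' @param n_patches patches per class.
#' @param seed RNG seed.
#' @return list with `separation` (minimum ratio of between-class distance
#'   to mean within-class spread over all class pairs) and the per-pair
#'   ratio matrix.
#' @export
class_separation <- function(classes = phantom_classes(), patch_size = 37L,
                             n_patches = 20L, seed = 1L) {
  with_seed(seed, {
    feats <- list()
    for (nm in names(classes)) {
      X <- t(vapply(seq_len(n_patches), function(i) {
        patch <- pmin(pmax(round(texture_field(c(patch_size, patch_size),
                                               classes[[nm]])), 0), 255)
        extract_features(patch)
      }, numeric(7)))
      feats[[nm]] <- X
    }
    all <- do.call(rbind, feats)
    ctr <- colMeans(all); scl <- apply(all, 2, stats::sd)
    scl[scl <= 0] <- 1
    feats <- lapply(feats, function(X) sweep(sweep(X, 2, ctr), 2, scl, "/"))
    cents <- lapply(feats, colMeans)
    spread <- vapply(names(feats), function(nm)
      mean(sqrt(rowSums(sweep(feats[[nm]], 2, cents[[nm]])^2))), numeric(1))
    k <- length(feats)
    ratio <- matrix(NA_real_, k, k, dimnames = list(names(feats), names(feats)))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dist_ij <- sqrt(sum((cents[[i]] - cents[[j]])^2))
      ratio[i, j] <- ratio[j, i] <-
        dist_ij / mean(c(spread[i], spread[j]))
    }
    list(separation = min(ratio, na.rm = TRUE), ratios = ratio)
  })
}
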