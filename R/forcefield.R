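# External force-field synthesis.
#
# The external energy driving the snake is
#   energy(x) = -exp(-eta * T(x)) * sum_i delta_i * e_i(x)
# where e_i are edge-strength maps normalized to [0, 1] (a gradient term and
# a texture-classification term), delta_i >= 0 their weights, and T the
# Euclidean distance (px) to the eroded rasterization of the user's initial
# annotation. The modulation factor is 1 on/inside the annotation and decays
# away from it, so minima of the energy sit on strong edges near the user's
# rough outline; eta = 0 switches the modulation off and recovers the
# classic gradient-edge field.

#' Classify all image blocks with a trained texture model
#'
#' The image is tiled with non-overlapping `block_size` blocks; each block's
#' texture features are classified with the one-vs-one model.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param model a `maxmargin_multiclass` from [train_multiclass()] or
#'   [train_model()].
#' @param block_size block side in pixels.
#' @param stride grid step of the classified blocks; the default
#'   `block_size` gives the non-overlapping tiling, a smaller stride an
#'   overlapping grid with finer label resolution.
#' @param levels,offsets co-occurrence settings, see [extract_features()].
#' @return an object of class `block_label_map`: list with `labels`
#'   (character matrix on the block grid), `block_size`, `stride`,
#'   `image_shape`, and `margin` (mean absolute pairwise decision value per
#'   block).
#' @export
classify_blocks <- function(image, model, block_size = 37L,
                            stride = block_size, levels = 32L,
                            offsets = glcm_offsets()) {
  px <- as_pixels(image)
  blocks <- sample_blocks(px, block_size, stride = stride)
  X <- feature_matrix(blocks, levels = levels, offsets = offsets)
  pred <- predict_multiclass(model, X, margins = TRUE)
  gr <- (nrow(px) - block_size) %/% stride + 1L
  gc <- (ncol(px) - block_size) %/% stride + 1L
  labels <- matrix(pred$label, gr, gc, byrow = TRUE)
  margin <- matrix(
    pred$margin[cbind(seq_along(pred$label), match(pred$label, model$class_names))],
    gr, gc, byrow = TRUE)
  structure(list(labels = labels, block_size = as.integer(block_size),
                 stride = as.integer(stride),
                 image_shape = dim(px), margin = margin),
            class = "block_label_map")
}

# Map pixel indices to the nearest block-grid cell (by block center).
grid_index <- function(n_pixels, n_cells, block_size, stride) {
  ctr <- (seq_len(n_cells) - 1L) * stride + (block_size + 1) / 2
  idx <- round(((seq_len(n_pixels)) - (block_size + 1) / 2) / stride) + 1L
  pmin(pmax(idx, 1L), n_cells)
}

#' Majority-vote smoothing of a block label map
#'
#' Each cell is relabeled to the label that holds strictly more than half of
#' the valid (in-bounds) cells of its `window` x `window` neighborhood (a
#' dynamic vote limit of `floor(n_valid / 2) + 1`); otherwise it keeps its
#' label. Passes repeat until a fixed point or `max_passes`.
#'
#' @param map a `block_label_map` (or plain character matrix).
#' @param window odd window side, >= 3.
#' @param max_passes maximum number of passes.
#' @return the smoothed object, same type as the input.
#' @export
majority_filter <- function(map, window = 3L, max_passes = 10L) {
  labels <- if (inherits(map, "block_label_map")) map$labels else map
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  h <- (window - 1L) %/% 2L
  nr <- nrow(labels); nc <- ncol(labels)
  for (pass in seq_len(max_passes)) {
    out <- labels
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      win <- labels[max(1, r - h):min(nr, r + h),
                    max(1, cc - h):min(nc, cc + h)]
      tab <- table(win)
      lim <- length(win) %/% 2 + 1
      top <- names(tab)[tab >= lim]
      if (length(top) == 1) out[r, cc] <- top
    }
    if (identical(out, labels)) { labels <- out; break }
    labels <- out
  }
  if (inherits(map, "block_label_map")) { map$labels <- labels; map }
  else labels
}

#' Render a block label map as a class-coded grayscale image
#'
#' Each pixel takes the greylevel of the grid cell whose block center is
#' nearest; with the tiling stride this is the block the pixel falls in,
#' and border pixels beyond the tiling inherit the nearest block's level.
#'
#' @param map a `block_label_map`.
#' @param class_greylevels named numeric vector mapping every label to a
#'   greylevel in `[0, 255]`.
#' @return a [gray_image()] of the map's `image_shape`.
#' @export
label_map_to_image <- function(map, class_greylevels) {
  labels <- map$labels
  missing <- setdiff(unique(as.vector(labels)), names(class_greylevels))
  if (length(missing))
    stop("no greylevel assigned to label(s): ", paste(missing, collapse = ", "))
  bs <- map$block_size
  st <- map$stride %||% bs
  n <- map$image_shape[1]; m <- map$image_shape[2]
  ridx <- grid_index(n, nrow(labels), bs, st)
  cidx <- grid_index(m, ncol(labels), bs, st)
  lv <- matrix(class_greylevels[labels], nrow(labels), ncol(labels))
  gray_image(lv[ridx, cidx, drop = FALSE])
}

# Evenly spaced greylevels for a class list (0 .. 255).
default_greylevels <- function(class_names) {
  k <- length(class_names)
  lv <- if (k == 1) 255 else round(seq(0, 255, length.out = k))
  names(lv) <- class_names
  lv
}

# Shift a matrix by (dr, dc), zero-padding.
shift_mat <- function(m, dr, dc) {
  n <- nrow(m); k <- ncol(m)
  out <- matrix(0, n, k)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(k, k + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Sobel gradient of a matrix: list(gr, gc, mag).
sobel_gradient <- function(m) {
  kr <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE) / 8
  gr <- EBImage::filter2(m, kr, boundary = "replicate")
  gc <- EBImage::filter2(m, t(kr), boundary = "replicate")
  list(gr = gr, gc = gc, mag = sqrt(gr^2 + gc^2))
}

# Canny edge detector: Gaussian smoothing, Sobel gradient, non-maximum
# suppression along the quantized gradient direction, and hysteresis
# thresholding with thresholds at quantiles of the nonzero gradient
# magnitudes (weak edges are kept only in connected components containing a
# strong edge).
canny_edges <- function(m, sigma = 1, quantiles = c(0.70, 0.90)) {
  g <- EBImage::gblur(m, sigma = sigma)
  sb <- sobel_gradient(g)
  mag <- sb$mag
  nz <- mag[mag > 1e-12]
  if (length(nz) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  ang <- atan2(sb$gc, sb$gr)  # direction of the gradient, (row, col) frame
  sector <- (round(ang / (pi / 4)) %% 4)
  steps <- list(`0` = c(1L, 0L), `1` = c(1L, 1L), `2` = c(0L, 1L),
                `3` = c(-1L, 1L))
  nms <- matrix(FALSE, nrow(m), ncol(m))
  for (s in 0:3) {
    st <- steps[[as.character(s)]]
    fwd <- shift_mat(mag, st[1], st[2])
    bwd <- shift_mat(mag, -st[1], -st[2])
    nms <- nms | (sector == s & mag >= fwd & mag >= bwd)
  }
  lo <- stats::quantile(nz, quantiles[1], names = FALSE)
  hi <- stats::quantile(nz, quantiles[2], names = FALSE)
  weak <- nms & mag >= lo
  strong <- nms & mag >= hi
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(matrix(as.numeric(weak), nrow(m), ncol(m)))
  keep <- setdiff(unique(lab[strong]), 0)
  matrix(lab %in% keep, nrow(m), ncol(m))
}

#' Gradient edge term f1
#'
#' Magnitude of the gradient of the Gaussian-smoothed image,
#' `||grad(G_sigma * I)||`, max-normalized to `[0, 1]`.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return edge-strength matrix in `[0, 1]`.
#' @export
edge_term_f1 <- function(image, sigma = 23) {
  if (sigma <= 0) stop("sigma must be > 0")
  px <- as_pixels(image) / 255
  g <- EBImage::gblur(px, sigma = sigma)
  mag <- sobel_gradient(g)$mag
  mx <- max(mag)
  if (mx <= 1e-15) matrix(0, nrow(px), ncol(px)) else mag / mx
}

#' Texture-classification edge term f2
#'
#' Turns a class-coded greylevel image (the rendered block classification)
#' into an edge-strength map: Gaussian smoothing of the blocky region
#' boundaries, local-mean adaptive thresholding, Canny edge detection, and a
#' final Gaussian diffusion of the binary edges (max-normalized to `[0, 1]`)
#' that widens their capture range.
#'
#' @param class_image a [gray_image()], typically from
#'   [label_map_to_image()].
#' @param smooth_sigma Gaussian scale of the boundary smoothing (px).
#' @param thresh_window side of the local-mean thresholding window (px);
#'   it must exceed the diameter of the largest object of interest, or the
#'   object's interior (which equals its own local mean) falls below the
#'   threshold and only a band along the boundary survives binarization.
#'   The window is clamped to the image size.
#' @param thresh_offset threshold offset above the local mean, on the
#'   `[0, 1]` intensity scale. The default is a tiny positive value: at an
#'   offset of exactly zero, floating-point noise in uniform areas (where
#'   the smoothed image equals its own local mean) binarizes into speckle
#'   that the edge detector then amplifies.
#' @param canny_sigma Gaussian scale inside the Canny detector (px).
#' @param canny_quantiles hysteresis thresholds, as quantiles of the nonzero
#'   gradient magnitudes (low, high).
#' @param capture_sigma Gaussian scale of the final edge diffusion (px).
#' @return edge-strength matrix in `[0, 1]` (all zero when the class image
#'   is constant).
#' @export
edge_term_f2 <- function(class_image, smooth_sigma = 2, thresh_window = 151,
                         thresh_offset = 1e-6,
                         canny_sigma = 1, canny_quantiles = c(0.70, 0.90),
                         capture_sigma = 6) {
  px <- as_pixels(class_image) / 255
  s <- EBImage::gblur(px, sigma = smooth_sigma)
  w <- as.integer(min(thresh_window, nrow(px) - 1L, ncol(px) - 1L))
  if (w %% 2L == 0L) w <- w - 1L
  if (w < 3L) w <- 3L
  localmean <- EBImage::filter2(s, matrix(1 / (w * w), w, w),
                                boundary = "replicate")
  binim <- matrix(as.numeric(s > localmean + thresh_offset),
                  nrow(px), ncol(px))
  edges <- canny_edges(binim, sigma = canny_sigma, quantiles = canny_quantiles)
  if (!any(edges)) return(matrix(0, nrow(px), ncol(px)))
  diffused <- EBImage::gblur(matrix(as.numeric(edges), nrow(px), ncol(px)),
                             sigma = capture_sigma)
  diffused[diffused < 0] <- 0  # FFT ringing can undershoot slightly
  diffused / max(diffused)
}

#' Annotation distance term T
#'
#' The initial user contour is rasterized to a filled binary mask, eroded by
#' a disk, and the Euclidean distance transform of the eroded mask is
#' returned: `T(x)` is the distance (px) from pixel `x` to the nearest
#' foreground pixel, 0 on the mask itself. If the erosion empties the mask,
#' the unfilled (uneroded) mask is used instead.
#'
#' @param contour n x 2 matrix of (row, col) points, implicitly closed.
#' @param image_shape `(n_rows, n_cols)`.
#' @param erosion_radius disk radius of the erosion, px (0 disables).
#' @return numeric distance matrix, >= 0.
#' @export
annotation_term <- function(contour, image_shape, erosion_radius = 3L) {
  mask <- contour_to_mask(contour, image_shape)
  if (sum(mask) == 0) stop("degenerate contour: rasterizes to an empty mask")
  b <- matrix(as.numeric(mask), image_shape[1], image_shape[2])
  if (erosion_radius >= 1) {
    er <- EBImage::erode(b, EBImage::makeBrush(2L * as.integer(erosion_radius) + 1L,
                                               shape = "disc"))
    if (sum(er) > 0) b <- er
  }
  distance_to_mask(b > 0)
}

#' Euclidean distance transform to a mask
#'
#' Distance from each pixel to the nearest foreground pixel of `mask`
#' (0 on the mask).
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @return numeric matrix of distances.
#' @export
distance_to_mask <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) stop("mask has no foreground pixels")
  as.matrix(EBImage::distmap(1 - m))
}

#' Compose the external energy field
#'
#' `energy = -exp(-eta * T) * sum_i delta_i * e_i`, with `e_i` edge-strength
#' maps in `[0, 1]`. The energy is everywhere <= 0; `eta = 0` (or a missing
#' `T`) disables the annotation modulation.
#'
#' @param edge_terms list of edge-strength matrices (same shape).
#' @param delta nonnegative weights, one per edge term.
#' @param T optional annotation distance matrix from [annotation_term()].
#' @param eta decay rate of the annotation modulation, per pixel (>= 0).
#' @return an object of class `force_field`: list with `energy`, `terms`
#'   (the inputs), and `params`.
#' @export
compose_external_energy <- function(edge_terms, delta, T = NULL, eta = 0) {
  if (!is.list(edge_terms)) edge_terms <- list(edge_terms)
  if (length(delta) != length(edge_terms))
    stop("need one delta weight per edge term")
  if (any(delta < 0)) stop("delta weights must be >= 0")
  if (eta < 0) stop("eta must be >= 0")
  shp <- dim(edge_terms[[1]])
  for (e in edge_terms)
    if (!identical(dim(e), shp)) stop("edge terms differ in shape")
  if (!is.null(T) && !identical(dim(T), shp))
    stop("T differs in shape from the edge terms")
  pi_f <- matrix(0, shp[1], shp[2])
  for (i in seq_along(edge_terms)) pi_f <- pi_f + delta[i] * edge_terms[[i]]
  modulation <- if (is.null(T) || eta == 0) 1 else exp(-eta * T)
  energy <- -modulation * pi_f
  structure(list(energy = energy,
                 terms = list(edges = edge_terms, T = T,
                              modulation = modulation),
                 params = list(delta = delta, eta = eta)),
            class = "force_field")
}
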