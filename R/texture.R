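# Block sampling and gray-level co-occurrence (Haralick) texture features.
#
# The feature vector used throughout the package has seven components, in
# this order:
#   mean, std            -- first-order statistics of the raw block
#                           intensities (population standard deviation)
#   contrast, idm,
#   correlation,
#   entropy, asm         -- second-order statistics of the normalized
#                           co-occurrence matrix, averaged over the
#                           configured offsets
FEATURE_NAMES <- c("mean", "std", "contrast", "idm", "correlation",
                   "entropy", "asm")

#' Default co-occurrence offsets
#'
#' Distance-1 displacements along 0, 45, 90 and 135 degrees, expressed as
#' (drow, dcol) pairs. Co-occurrence matrices are accumulated symmetrically,
#' so these four directions cover all eight distance-1 neighbors.
#'
#' @return a 4 x 2 integer matrix of (drow, dcol) offsets.
#' @export
glcm_offsets <- function() {
  matrix(c(0L, 1L,   # 0 degrees
           -1L, 1L,  # 45 degrees
           -1L, 0L,  # 90 degrees
           -1L, -1L),# 135 degrees
         ncol = 2, byrow = TRUE)
}

#' Sample square blocks from an image
#'
#' The image is raster-scanned row-major and every fully contained
#' `block_size` x `block_size` window on the stride grid is returned.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param block_size side of the square block, in pixels.
#' @param stride grid step in pixels; `stride = block_size` gives a
#'   non-overlapping tiling.
#' @return list of blocks; each block is a list with `pixels` (matrix) and
#'   `origin` (top-left (row, col), 1-based).
#' @export
sample_blocks <- function(image, block_size, stride = block_size) {
  px <- as_pixels(image)
  n <- nrow(px); m <- ncol(px)
  if (block_size < 1 || stride < 1) stop("block_size and stride must be >= 1")
  if (block_size > n || block_size > m)
    stop("block_size (", block_size, ") exceeds image dimensions (",
         n, " x ", m, ")")
  rows <- seq.int(1L, n - block_size + 1L, by = stride)
  cols <- seq.int(1L, m - block_size + 1L, by = stride)
  out <- vector("list", length(rows) * length(cols))
  k <- 1L
  for (r in rows) for (cc in cols) {
    out[[k]] <- list(pixels = px[r:(r + block_size - 1L),
                                 cc:(cc + block_size - 1L), drop = FALSE],
                     origin = c(r, cc))
    k <- k + 1L
  }
  out
}

# Quantize 8-bit intensities to `levels` equal-width bins over [0, 255],
# returning bin indices in 0 .. levels-1.
quantize_levels <- function(pixels, levels) {
  q <- floor(pixels * levels / 256)
  q[q > levels - 1] <- levels - 1
  q[q < 0] <- 0
  q
}

#' Normalized gray-level co-occurrence matrix
#'
#' Intensities are quantized to `levels` equal-width bins over `[0, 255]`;
#' intensity pairs are counted symmetrically (both `(i, j)` and `(j, i)`) for
#' every offset, and the joint matrix is normalized to sum to 1.
#'
#' @param block block pixels: a numeric matrix, or a block as returned by
#'   [sample_blocks()].
#' @param levels number of quantization bins (>= 2).
#' @param offsets k x 2 matrix of (drow, dcol) displacements.
#' @return `levels` x `levels` symmetric matrix summing to 1.
#' @export
cooccurrence <- function(block, levels = 32L, offsets = glcm_offsets()) {
  px <- if (is.list(block)) block$pixels else as_pixels(block)
  if (levels < 2) stop("levels must be >= 2")
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (nrow(offsets) < 1) stop("at least one offset is required")
  q <- quantize_levels(px, levels)
  n <- nrow(q); m <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    r1 <- max(1L, 1L - dr):min(n, n - dr)
    c1 <- max(1L, 1L - dc):min(m, m - dc)
    if (length(r1) < 1 || length(c1) < 1) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    idx <- a * levels + b + 1  # 1-based linear index into levels x levels
    tab <- tabulate(idx, nbins = levels * levels)
    inc <- matrix(tab, levels, levels, byrow = TRUE)
    counts <- counts + inc + t(inc)  # symmetric accumulation
  }
  s <- sum(counts)
  if (s == 0) stop("no valid pixel pairs for the given offsets")
  counts / s
}

# Haralick statistics of one normalized co-occurrence matrix.
glcm_stats <- function(p) {
  levels <- nrow(p)
  i <- matrix(0:(levels - 1), levels, levels)
  j <- t(i)
  d2 <- (i - j)^2
  contrast <- sum(d2 * p)
  idm <- sum(p / (1 + d2))
  pi_ <- rowSums(p)
  mu_i <- sum((0:(levels - 1)) * pi_)
  var_i <- sum(((0:(levels - 1)) - mu_i)^2 * pi_)
  # marginals are equal by symmetry
  correlation <- if (var_i <= 0) 0 else
    sum((i - mu_i) * (j - mu_i) * p) / var_i
  nz <- p[p > 0]
  entropy <- -sum(nz * log(nz))
  asm <- sum(p^2)
  c(contrast = contrast, idm = idm, correlation = correlation,
    entropy = entropy, asm = asm)
}

#' Extract the 7-component texture feature vector of a block
#'
#' First-order statistics (mean, population standard deviation) are computed
#' on the raw, unquantized intensities. The Haralick terms (contrast, inverse
#' difference moment, correlation, entropy in nats, angular second moment)
#' are computed per offset on the normalized co-occurrence matrix and
#' averaged over the offsets. The correlation of a constant block is defined
#' as 0.
#'
#' @inheritParams cooccurrence
#' @return named numeric vector of length 7
#'   (mean, std, contrast, idm, correlation, entropy, asm).
#' @export
extract_features <- function(block, levels = 32L, offsets = glcm_offsets()) {
  px <- if (is.list(block)) block$pixels else as_pixels(block)
  offsets <- matrix(as.integer(offsets), ncol = 2)
  mu <- mean(px)
  sigma <- sqrt(mean((px - mu)^2))
  acc <- numeric(5)
  for (k in seq_len(nrow(offsets))) {
    p <- cooccurrence(px, levels = levels, offsets = offsets[k, , drop = FALSE])
    acc <- acc + glcm_stats(p)
  }
  acc <- acc / nrow(offsets)
  out <- c(mu, sigma, acc)
  names(out) <- FEATURE_NAMES
  out
}

#' Feature matrix for a list of blocks
#'
#' @param blocks list of blocks from [sample_blocks()].
#' @inheritParams cooccurrence
#' @return numeric matrix, one row per block, columns named as in
#'   [extract_features()].
#' @export
feature_matrix <- function(blocks, levels = 32L, offsets = glcm_offsets()) {
  out <- t(vapply(blocks, extract_features, numeric(7),
                  levels = levels, offsets = offsets))
  colnames(out) <- FEATURE_NAMES
  out
}
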