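# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's vectorized code
# paths: the co-occurrence oracle counts pixel pairs one by one, the
# feature oracle evaluates the textbook formulas with explicit loops.

# Brute-force symmetric co-occurrence matrix.
oracle_cooccurrence <- function(pixels, levels, offsets) {
  q <- floor(pixels * levels / 256)
  q[q > levels - 1] <- levels - 1
  counts <- matrix(0, levels, levels)
  n <- nrow(q); m <- ncol(q)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    for (r in seq_len(n)) for (cc in seq_len(m)) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m) {
        i <- q[r, cc] + 1; j <- q[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts / sum(counts)
}

# Brute-force Haralick statistics of one normalized co-occurrence matrix.
oracle_glcm_stats <- function(p) {
  levels <- nrow(p)
  contrast <- 0; idm <- 0; entropy <- 0; asm <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:levels) for (j in 1:levels) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  var_i <- 0; var_j <- 0; cov_ij <- 0
  for (i in 1:levels) for (j in 1:levels) {
    v <- p[i, j]
    contrast <- contrast + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    if (v > 0) entropy <- entropy - v * log(v)
    asm <- asm + v^2
    var_i <- var_i + ((i - 1) - mu_i)^2 * v
    var_j <- var_j + ((j - 1) - mu_j)^2 * v
    cov_ij <- cov_ij + ((i - 1) - mu_i) * ((j - 1) - mu_j) * v
  }
  corr <- if (var_i * var_j <= 0) 0 else cov_ij / sqrt(var_i * var_j)
  c(contrast = contrast, idm = idm, correlation = corr,
    entropy = entropy, asm = asm)
}

# Brute-force 7-feature vector, averaging Haralick terms over the offsets.
oracle_features <- function(pixels, levels = 32L, offsets = glcm_offsets()) {
  mu <- mean(pixels)
  sigma <- sqrt(sum((pixels - mu)^2) / length(pixels))
  acc <- numeric(5)
  for (k in seq_len(nrow(offsets))) {
    p <- oracle_cooccurrence(pixels, levels, offsets[k, , drop = FALSE])
    acc <- acc + oracle_glcm_stats(p)
  }
  unname(c(mu, sigma, acc / nrow(offsets)))
}

# The 4 x 4 two-column test block: left half 0, right half 255.
two_column_block <- function() {
  matrix(c(0, 0, 255, 255), 4, 4, byrow = TRUE)
}

# Synthetic disk image: intensity `inside` on a disk, `outside` elsewhere.
disk_image <- function(shape, center, radius, inside = 60, outside = 200) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  m <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  img <- matrix(outside, shape[1], shape[2])
  img[m] <- inside
  list(image = img, mask = m)
}

circle_contour <- function(center, radius, n = 64) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(t), center[2] + radius * sin(t))
}

# Separable two-class Gaussian blobs.
separable_blobs <- function(n_per_class, dim = 2, gap = 6) {
  X <- rbind(matrix(rnorm(n_per_class * dim), n_per_class, dim),
             sweep(matrix(rnorm(n_per_class * dim), n_per_class, dim),
                   2, rep(gap, dim), "+"))
  y <- rep(c(-1, 1), each = n_per_class)
  list(X = X, y = y)
}

# Standard phantom study fixtures: training items and a trained model,
# cached per session to keep the suite fast.
phantom_training_items <- function(seeds = 1001:1006) {
  lapply(seeds, function(s) {
    p <- generate_phantom(phantom_preset("biopsy", seed = s))
    list(image = p$image, annotations = p$annotations)
  })
}

cached_phantom_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- train_model(phantom_training_items(), phantom_config())
    cache
  }
})
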