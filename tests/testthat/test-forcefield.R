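test_that("the distance transform gives exact 3-4-5 distances and is 0 on the mask", {
  m <- matrix(FALSE, 20, 30)
  m[10, 10] <- TRUE
  T <- distance_to_mask(m)
  expect_equal(T[10, 13], 3)
  expect_equal(T[13, 14], 5)
  expect_equal(T[10, 10], 0)

  set.seed(3)
  mm <- matrix(runif(400) < 0.1, 20, 20)
  mm[5, 5] <- TRUE
  Tm <- distance_to_mask(mm)
  expect_true(all(Tm[mm] == 0))
})

test_that("the distance transform is 1-Lipschitz", {
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.05, 30, 30)
    m[sample(900, 1)] <- TRUE
    T <- distance_to_mask(m)
    idx <- cbind(sample(30, 40, TRUE), sample(30, 40, TRUE))
    jdx <- cbind(sample(30, 40, TRUE), sample(30, 40, TRUE))
    d <- sqrt(rowSums((idx - jdx)^2))
    expect_true(all(abs(T[idx] - T[jdx]) <= d + 1e-9))
  }
})

test_that("the annotation term rasterizes, erodes and falls back correctly", {
  sq <- cbind(c(30, 30, 70, 70), c(30, 70, 70, 30))
  T <- annotation_term(sq, c(100, 100), erosion_radius = 3)
  expect_equal(T[50, 50], 0)            # interior
  expect_gt(T[50, 80], 0)               # outside
  # erosion shrinks the zero set: boundary pixels are now at distance > 0
  expect_gt(T[30, 50], 0)
  # a tiny contour whose erosion would be empty falls back to the mask
  tiny <- cbind(c(10, 10, 12, 12), c(10, 12, 12, 10))
  Tt <- annotation_term(tiny, c(20, 20), erosion_radius = 5)
  expect_equal(Tt[11, 11], 0)
})

test_that("the composed energy obeys its closed form and sign", {
  z <- matrix(0, 10, 10)
  expect_true(all(compose_external_energy(list(z), 1)$energy == 0))

  set.seed(5)
  e1 <- matrix(runif(100), 10, 10)
  f <- compose_external_energy(list(e1), 1, T = NULL, eta = 0)
  expect_equal(f$energy, -e1)

  T <- matrix(0, 10, 10); T[1, 1] <- 10
  f2 <- compose_external_energy(list(e1 * 0 + 1), 1, T = T, eta = 1)
  expect_equal(f2$energy[1, 1] / f2$energy[2, 2], exp(-10))
  expect_true(all(f2$energy <= 0))

  # monotone in delta; |energy| non-increasing in T
  fa <- compose_external_energy(list(e1), 0.5, T = T, eta = 0.1)
  fb <- compose_external_energy(list(e1), 1.0, T = T, eta = 0.1)
  expect_true(all(fb$energy <= fa$energy + 1e-15))
  expect_true(all(abs(fb$energy[1, 1]) <= abs(-e1[1, 1]) + 1e-15))

  expect_error(compose_external_energy(list(e1, matrix(0, 5, 5)), c(1, 1)),
               "shape")
  expect_error(compose_external_energy(list(e1), -1), ">= 0")
})

test_that("eta = 0 reproduces the classic gradient field exactly", {
  d <- disk_image(c(80, 80), c(40, 40), 22)
  e1 <- edge_term_f1(d$image, sigma = 3)
  T <- distance_to_mask(d$mask)
  classic <- compose_external_energy(list(e1), 0.6)
  modulated <- compose_external_energy(list(e1), 0.6, T = T, eta = 0)
  expect_equal(modulated$energy, classic$energy, tolerance = 1e-12)
})

test_that("f1 is zero on constant images and peaks on a step edge", {
  expect_true(all(edge_term_f1(matrix(7, 30, 30), sigma = 2) == 0))
  img <- matrix(0, 40, 40); img[, 21:40] <- 200
  e <- edge_term_f1(img, sigma = 2)
  expect_true(all(e >= 0 & e <= 1))
  mid <- apply(e[10:30, ], 1, which.max)
  expect_true(all(abs(mid - 20.5) <= 1))
})

test_that("f2 ridges on the boundary of a square class region", {
  img <- matrix(0, 100, 100)
  img[31:70, 31:70] <- 200
  e <- edge_term_f2(img)
  expect_true(all(e >= 0 & e <= 1))
  expect_equal(max(e), 1)
  # mean distance of the f2 argmax ridge to the true square boundary
  ridge <- which(e > 0.9 * max(e), arr.ind = TRUE)
  db <- function(p) {
    r <- p[1]; cc <- p[2]
    if (r >= 31 && r <= 70 && cc >= 31 && cc <= 70)
      min(r - 31, 70 - r, cc - 31, 70 - cc)
    else sqrt(max(0, 31 - r, r - 70)^2 + max(0, 31 - cc, cc - 70)^2)
  }
  expect_lte(mean(apply(ridge, 1, db)), 2)

  expect_true(all(edge_term_f2(matrix(128, 60, 60)) == 0))
})

test_that("majority filtering relabels minorities and is stable on uniform maps", {
  m <- matrix("a", 3, 3); m[2, 2] <- "b"
  expect_true(all(majority_filter(m, 3, 1) == "a"))
  u <- matrix("x", 5, 5)
  expect_identical(majority_filter(u, 3, 5), u)
  # checkerboard: reaches a fixed point within the pass budget
  cb <- matrix(ifelse((outer(1:6, 1:6, "+") %% 2) == 0, "a", "b"), 6, 6)
  s1 <- majority_filter(cb, 3, 20)
  expect_identical(majority_filter(s1, 3, 1), s1)
  # no label is invented
  set.seed(6)
  r <- matrix(sample(c("p", "q", "r"), 49, TRUE), 7, 7)
  expect_true(all(majority_filter(r, 3, 3) %in% unique(as.vector(r))))
})

test_that("label maps render to class-coded images and back", {
  map <- structure(list(labels = matrix(c("A", "B", "B", "A"), 2, 2),
                        block_size = 5L, stride = 5L,
                        image_shape = c(10L, 10L)),
                   class = "block_label_map")
  img <- label_map_to_image(map, c(A = 0, B = 255))
  expect_true(all(img[1:5, 1:5] == 0))
  expect_true(all(img[1:5, 6:10] == 255))
  expect_true(all(img[6:10, 1:5] == 255))
  expect_true(all(img[6:10, 6:10] == 0))
  expect_error(label_map_to_image(map, c(A = 0)), "B")
})

test_that("classified block grids have the expected shape and uniformity", {
  set.seed(14)
  # two trivially different textures: dark vs bright noise
  mk <- function(mu) matrix(pmin(pmax(round(rnorm(37 * 37 * 4, mu, 6)), 0), 255),
                            74, 74)
  X <- rbind(feature_matrix(sample_blocks(mk(60), 37, 6)),
             feature_matrix(sample_blocks(mk(190), 37, 6)))
  y <- rep(c("dark", "bright"), each = nrow(X) / 2)
  mc <- train_multiclass(X, y)
  lm <- classify_blocks(mk(60), mc, 37)
  expect_equal(dim(lm$labels), c(2, 2))
  expect_true(all(lm$labels == "dark"))
  lm2 <- classify_blocks(mk(190), mc, 37)
  expect_true(all(lm2$labels == "bright"))
  # constant image: identical features, hence one label everywhere
  lu <- classify_blocks(matrix(60, 111, 74), mc, 37)
  expect_equal(dim(lu$labels), c(3, 2))
  expect_length(unique(as.vector(lu$labels)), 1L)
})
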