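test_that("block sampling tiles the image row-major with full blocks only", {
  img <- matrix(0, 74, 74)
  b <- sample_blocks(img, 37, 37)
  expect_length(b, 4)
  expect_equal(lapply(b, `[[`, "origin"),
               list(c(1, 1), c(1, 38), c(38, 1), c(38, 38)))
  expect_length(sample_blocks(matrix(0, 37, 37), 37), 1)
  expect_error(sample_blocks(matrix(0, 36, 100), 37), "exceeds")
  # partial blocks at the far edge are dropped
  expect_length(sample_blocks(matrix(0, 80, 40), 37, 37), 2)
})

test_that("co-occurrence matrix matches hand-counted pairs", {
  blk <- two_column_block()
  p <- cooccurrence(blk, levels = 2, offsets = matrix(c(0, 1), 1))
  expect_equal(p[1, 1], 1 / 3)
  expect_equal(p[1, 2], 1 / 6)
  expect_equal(p[2, 1], 1 / 6)
  expect_equal(p[2, 2], 1 / 3)

  const <- matrix(100, 5, 5)
  pc <- cooccurrence(const, levels = 8)
  expect_equal(sum(pc), 1)
  expect_equal(pc[4, 4], 1)  # level 100 quantizes to bin 3 (0-based)
})

test_that("co-occurrence is symmetric, nonnegative and sums to 1", {
  set.seed(7)
  for (i in 1:10) {
    blk <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    p <- cooccurrence(blk, levels = 16)
    expect_equal(sum(p), 1)
    expect_equal(p, t(p))
    expect_true(all(p >= 0))
  }
})

test_that("features of the hand-computed blocks are exact", {
  f <- extract_features(two_column_block(), levels = 2,
                        offsets = matrix(c(0, 1), 1))
  expect_equal(unname(f["mean"]), 127.5)
  expect_equal(unname(f["std"]), 127.5)
  expect_equal(unname(f["contrast"]), 1 / 3)
  expect_equal(unname(f["idm"]), 5 / 6)
  expect_equal(unname(f["correlation"]), 1 / 3)
  expect_equal(unname(f["entropy"]), (2 / 3) * log(3) + (1 / 3) * log(6))
  expect_equal(unname(f["asm"]), 5 / 18)

  fc <- extract_features(matrix(100, 6, 6))
  expect_equal(unname(fc), c(100, 0, 0, 1, 0, 0, 1))
})

test_that("features agree with the brute-force oracle on random blocks", {
  set.seed(11)
  for (i in 1:25) {
    blk <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_equal(unname(extract_features(blk, levels = 8)),
                 oracle_features(blk, levels = 8),
                 tolerance = 1e-9)
  }
})

test_that("feature ranges and origin invariance hold", {
  set.seed(13)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  for (i in 1:10) {
    blk <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
    f <- extract_features(blk, levels = 8)
    expect_true(f["asm"] > 0 && f["asm"] <= 1)
    expect_true(f["idm"] > 0 && f["idm"] <= 1)
    expect_true(f["entropy"] >= 0 && f["entropy"] <= log(64))
    expect_true(f["contrast"] >= 0)
    expect_true(abs(f["correlation"]) <= 1 + 1e-12)
  }
  b <- sample_blocks(img, 7, 7)
  f1 <- extract_features(b[[1]])
  f2 <- extract_features(list(pixels = b[[1]]$pixels, origin = c(99, 99)))
  expect_identical(f1, f2)
})
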