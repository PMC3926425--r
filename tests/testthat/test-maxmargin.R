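test_that("kernel values match their closed forms", {
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 2), c(1, 2)), 5)
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 2), c(3, 4), c(3, 4)), 1)
  expect_equal(kernel_eval(kernel_spec("polynomial", gamma = 1, degree = 2),
                           c(1, 0), c(0, 1)), 1)
  expect_error(kernel_eval(kernel_spec("linear"), c(1, 2), c(1, 2, 3)),
               "dimension")
})

test_that("the symmetric two-point problem has its analytic solution", {
  m <- train_binary(matrix(c(0, 2), ncol = 1), c(-1, 1),
                    kernel_spec("linear"), cost = 10)
  expect_equal(sort(m$multipliers), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$bias, -1, tolerance = 1e-6)
  expect_equal(decision_value(m, 1), 0, tolerance = 1e-9)
  expect_equal(decision_value(m, 2), 1, tolerance = 1e-9)
  expect_equal(decision_value(m, 0), -1, tolerance = 1e-9)
  expect_identical(predict_binary(m, 3), 1L)
  expect_identical(predict_binary(m, -1), -1L)
  expect_identical(predict_binary(m, 1), 1L)  # sign(0) -> +1
})

test_that("training satisfies KKT constraints and separates separable data", {
  set.seed(5)
  for (i in 1:5) {
    d <- separable_blobs(10 + 2 * i, dim = 2 + i %% 3)
    m <- train_binary(d$X, d$y, kernel_spec("linear"), cost = 1.5)
    expect_lte(abs(sum(m$multipliers * m$sv_labels)), 1e-6)
    expect_true(all(m$multipliers > 0 & m$multipliers <= 1.5 + 1e-12))
    expect_equal(sum(predict_binary(m, d$X) != d$y), 0)
    f <- decision_value(m, m$support_vectors)
    on_margin <- m$multipliers < 1.5 - 1e-8
    expect_true(all(abs(m$sv_labels[on_margin] * f[on_margin] - 1) <= 1e-3))
  }
})

test_that("the dual objective matches an independent SVM solver", {
  skip_if_not_installed("e1071")
  set.seed(6)
  d <- separable_blobs(25, dim = 2, gap = 4)
  spec <- kernel_spec("linear")
  m <- train_binary(d$X, d$y, spec, cost = 1.5)
  ref <- e1071::svm(d$X, factor(d$y), kernel = "linear", cost = 1.5,
                    scale = FALSE)
  # rebuild the reference dual objective from its multipliers
  alpha_ref <- abs(ref$coefs[, 1])
  y_ref <- sign(ref$coefs[, 1])
  K <- d$X[ref$index, , drop = FALSE] %*% t(d$X[ref$index, , drop = FALSE])
  coef <- alpha_ref * y_ref
  dual_ref <- sum(alpha_ref) - 0.5 * sum(coef * (K %*% coef))
  expect_equal(m$dual_objective, dual_ref, tolerance = 1e-5)
  expect_equal(predict_binary(m, d$X),
               as.integer(as.character(predict(ref, d$X))))
})

test_that("the XOR pattern is separated by the RBF kernel", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), ncol = 2, byrow = TRUE)
  y <- c(1, 1, -1, -1)
  m <- train_binary(X, y, kernel_spec("rbf", gamma = 1), cost = 100)
  expect_equal(predict_binary(m, X), as.integer(y))
})

test_that("degenerate training inputs are rejected", {
  expect_error(train_binary(matrix(1:4, 2), c(1, 1), kernel_spec("linear")),
               "both classes")
  expect_error(train_binary(matrix(1, 1, 1), 1, kernel_spec("linear")),
               "two training points")
  expect_error(train_binary(matrix(1:4, 2), c(0, 2), kernel_spec("linear")),
               "labels")
})

test_that("growing the cost on separable data does not add training errors", {
  set.seed(8)
  d <- separable_blobs(20, gap = 5)
  errs <- vapply(c(0.5, 1.5, 10, 100), function(cc) {
    m <- train_binary(d$X, d$y, kernel_spec("linear"), cost = cc)
    sum(predict_binary(m, d$X) != d$y)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_equal(errs[[4]], 0)
})

test_that("a duplicated training point leaves predictions unchanged", {
  set.seed(9)
  d <- separable_blobs(15, gap = 5)
  m1 <- train_binary(d$X, d$y, kernel_spec("linear"), cost = 1.5)
  m2 <- train_binary(rbind(d$X, d$X[1, ]), c(d$y, d$y[1]),
                     kernel_spec("linear"), cost = 1.5)
  probe <- matrix(rnorm(40), 20, 2)
  expect_equal(decision_value(m1, probe), decision_value(m2, probe),
               tolerance = 1e-3)
})

test_that("one-vs-one multiclass separates Gaussian clusters", {
  set.seed(10)
  X <- rbind(matrix(rnorm(60), 30, 2),
             sweep(matrix(rnorm(60), 30, 2), 2, c(8, 0), "+"),
             sweep(matrix(rnorm(60), 30, 2), 2, c(0, 8), "+"))
  y <- rep(c("a", "b", "c"), each = 30)
  mc <- train_multiclass(X, y)
  expect_gte(mean(predict_multiclass(mc, X) == y), 0.95)
  # deterministic
  expect_identical(predict_multiclass(mc, X), predict_multiclass(mc, X))
})

test_that("two-class multiclass reduces to the binary model", {
  set.seed(12)
  d <- separable_blobs(15, gap = 5)
  y <- ifelse(d$y > 0, "pos", "neg")
  mc <- train_multiclass(d$X, y, scale = FALSE)
  mb <- train_binary(d$X, ifelse(y == "neg", 1, -1), kernel_spec("linear"),
                     cost = 1.5)  # "neg" < "pos": pair codes neg as +1
  probe <- matrix(rnorm(30), 15, 2)
  pred_mc <- predict_multiclass(mc, probe)
  pred_b <- ifelse(predict_binary(mb, probe) > 0, "neg", "pos")
  expect_identical(pred_mc, pred_b)
})

test_that("cross-validation folds are stratified and deterministic", {
  y <- rep(c("a", "b", "c"), times = c(40, 25, 11))
  f <- cv_folds(y, k = 5, seed = 3)
  expect_length(f, length(y))
  expect_setequal(unique(f), 1:5)
  for (cls in unique(y)) {
    per_fold <- table(f[y == cls])
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_identical(f, cv_folds(y, k = 5, seed = 3))
  expect_false(identical(f, cv_folds(y, k = 5, seed = 4)))
  expect_error(cv_folds(y, k = 1), ">= 2")
})
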