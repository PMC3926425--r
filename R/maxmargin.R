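# Maximum-margin kernel classifier: soft-margin dual problem
#
#   maximize  L_D = sum(lambda) - 1/2 sum_ij lambda_i lambda_j y_i y_j K(x_i, x_j)
#   s.t.      0 <= lambda_i <= c,  sum(lambda_i y_i) = 0
#
# solved by a deterministic Platt-style SMO. The decision function is
#   f(x) = sum_i lambda_i y_i K(x_i, x) + w0
# with w0 estimated from the KKT complementarity condition (on-margin
# support vectors satisfy y_i f(x_i) = 1).

#' Kernel specification
#'
#' @param kind one of `"linear"`, `"polynomial"`, `"rbf"`.
#' @param gamma positive scale: the multiplier of the inner product for the
#'   polynomial kernel `(gamma * <a,b> + 1)^degree`, and the width in the
#'   RBF kernel `exp(-||a - b||^2 / gamma)`.
#' @param degree polynomial degree (2 or 3).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "rbf"),
                        gamma = 1, degree = 2L) {
  kind <- match.arg(kind)
  if (kind != "linear") {
    if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  }
  if (kind == "polynomial" && !(degree %in% c(2L, 3L)))
    stop("polynomial degree must be 2 or 3")
  structure(list(kind = kind, gamma = gamma, degree = as.integer(degree)),
            class = "kernel_spec")
}

#' Evaluate a kernel between two feature vectors
#'
#' @param spec a [kernel_spec()].
#' @param a,b numeric vectors of equal length.
#' @return the scalar kernel value; for the RBF kernel it lies in `(0, 1]`.
#' @export
kernel_eval <- function(spec, a, b) {
  if (length(a) != length(b)) stop("kernel arguments differ in dimension")
  switch(spec$kind,
    linear = sum(a * b),
    polynomial = (spec$gamma * sum(a * b) + 1)^spec$degree,
    rbf = exp(-sum((a - b)^2) / spec$gamma))
}

# Kernel matrix between the rows of X and the rows of Z.
kernel_matrix <- function(spec, X, Z = X) {
  G <- X %*% t(Z)
  switch(spec$kind,
    linear = G,
    polynomial = (spec$gamma * G + 1)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * G
      d2[d2 < 0] <- 0
      exp(-d2 / spec$gamma)
    })
}

# Deterministic SMO solver for the dual problem. Returns lambda and bias.
smo_solve <- function(K, y, cost, tol = 1e-4, eps = 1e-12,
                      max_sweeps = 20000L) {
  n <- length(y)
  lambda <- numeric(n)
  b <- 0
  # error cache: E_i = f(x_i) - y_i; with lambda = 0, f = b = 0
  E <- -y

  take_step <- function(i1, i2) {
    if (i1 == i2) return(FALSE)
    a1 <- lambda[i1]; a2 <- lambda[i2]
    y1 <- y[i1]; y2 <- y[i2]
    E1 <- E[i1]; E2 <- E[i2]
    s <- y1 * y2
    if (s < 0) { L <- max(0, a2 - a1); H <- min(cost, cost + a2 - a1) }
    else       { L <- max(0, a1 + a2 - cost); H <- min(cost, a1 + a2) }
    if (L >= H) return(FALSE)
    k11 <- K[i1, i1]; k12 <- K[i1, i2]; k22 <- K[i2, i2]
    eta <- k11 + k22 - 2 * k12
    if (eta > eps) {
      a2new <- a2 + y2 * (E1 - E2) / eta
      a2new <- min(max(a2new, L), H)
    } else {
      # flat direction (e.g. duplicated points): no progress along this pair
      return(FALSE)
    }
    if (abs(a2new - a2) < eps * (a2new + a2 + eps)) return(FALSE)
    a1new <- a1 + s * (a2 - a2new)
    d1 <- y1 * (a1new - a1); d2 <- y2 * (a2new - a2)
    b1 <- b - (E1 + d1 * k11 + d2 * k12)
    b2 <- b - (E2 + d1 * k12 + d2 * k22)
    bnew <- if (a1new > eps && a1new < cost - eps) b1
            else if (a2new > eps && a2new < cost - eps) b2
            else (b1 + b2) / 2
    E <<- E + d1 * K[, i1] + d2 * K[, i2] + (bnew - b)
    lambda[i1] <<- a1new; lambda[i2] <<- a2new
    b <<- bnew
    E[i1] <<- sum(lambda * y * K[, i1]) + b - y1
    E[i2] <<- sum(lambda * y * K[, i2]) + b - y2
    TRUE
  }

  examine <- function(i2) {
    y2 <- y[i2]; a2 <- lambda[i2]; E2 <- E[i2]
    r2 <- E2 * y2
    if (!((r2 < -tol && a2 < cost) || (r2 > tol && a2 > 0))) return(FALSE)
    nb <- which(lambda > eps & lambda < cost - eps)
    if (length(nb) > 1) {
      i1 <- nb[which.max(abs(E[nb] - E2))]
      if (take_step(i1, i2)) return(TRUE)
    }
    # deterministic sweeps: non-bound first, then all, starting after i2
    start <- i2 %% length(y) + 1L
    idx <- c(start:length(y), seq_len(start - 1L))
    for (i1 in idx[idx %in% nb]) if (take_step(i1, i2)) return(TRUE)
    for (i1 in idx) if (take_step(i1, i2)) return(TRUE)
    FALSE
  }

  num_changed <- 0L
  examine_all <- TRUE
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps)
      stop("SMO did not converge within ", max_sweeps, " sweeps")
    num_changed <- 0L
    targets <- if (examine_all) seq_len(n)
               else which(lambda > eps & lambda < cost - eps)
    for (i2 in targets) num_changed <- num_changed + examine(i2)
    if (examine_all) {
      if (num_changed == 0L) break
      examine_all <- FALSE
    } else if (num_changed == 0L) {
      examine_all <- TRUE
    }
  }
  list(lambda = lambda, bias = b)
}

#' Train a binary maximum-margin classifier
#'
#' Solves the soft-margin dual problem for labels in `{-1, +1}` and returns
#' the support-vector expansion of the decision function. The returned
#' multipliers satisfy the box constraints exactly and balance to
#' `|sum(lambda_i * y_i)| <= 1e-6`.
#'
#' @param X numeric matrix, one feature vector per row.
#' @param y labels, coercible to `{-1, +1}`; both classes must be present.
#' @param spec a [kernel_spec()].
#' @param cost soft-margin cost parameter `c > 0` (default 1.5).
#' @param tol KKT tolerance of the solver.
#' @return an object of class `maxmargin_model` with elements
#'   `support_vectors`, `multipliers`, `sv_labels`, `bias`, `kernel`,
#'   `cost`, `dual_objective`, `dim`.
#' @export
train_binary <- function(X, y, spec = kernel_spec("linear"), cost = 1.5,
                         tol = 1e-4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) < 2) stop("at least two training points are required")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training set")
  if (cost <= 0) stop("cost must be > 0")
  K <- kernel_matrix(spec, X)
  sol <- smo_solve(K, y, cost, tol = tol)
  lambda <- sol$lambda
  coef <- lambda * y
  # refine bias: average KKT estimate over on-margin vectors
  on_margin <- which(lambda > 1e-8 & lambda < cost - 1e-8)
  f0 <- as.numeric(K %*% coef)
  b <- if (length(on_margin)) mean(y[on_margin] - f0[on_margin]) else sol$bias
  dual <- sum(lambda) - 0.5 * sum(coef * (K %*% coef))
  keep <- which(lambda > 1e-8)
  structure(
    list(support_vectors = X[keep, , drop = FALSE],
         multipliers = lambda[keep],
         sv_labels = as.integer(y[keep]),
         bias = b,
         dual_objective = dual,
         kernel = spec,
         cost = cost,
         dim = ncol(X)),
    class = "maxmargin_model")
}

#' Decision value of a binary model
#'
#' The signed distance surrogate `sum_i lambda_i y_i K(x_i, x) + w0`.
#'
#' @param model a `maxmargin_model`.
#' @param x a feature vector, or a matrix with one vector per row.
#' @return numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$dim)
    stop("feature dimension ", ncol(x), " does not match model (", model$dim, ")")
  if (nrow(model$support_vectors) == 0) return(rep(model$bias, nrow(x)))
  Kx <- kernel_matrix(model$kernel, x, model$support_vectors)
  as.numeric(Kx %*% (model$multipliers * model$sv_labels)) + model$bias
}

#' Predict the binary class of feature vectors
#'
#' Returns `sign(decision_value)`, with an exact zero mapped to `+1`.
#'
#' @inheritParams decision_value
#' @return integer vector of labels in `{-1, +1}`.
#' @export
predict_binary <- function(model, x) {
  f <- decision_value(model, x)
  ifelse(f >= 0, 1L, -1L)
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

#' Train a one-vs-one multi-class maximum-margin classifier
#'
#' One binary model is trained per unordered class pair (the first class of
#' the pair, in sorted order, is coded `+1`). Prediction is by majority vote
#' over the pairwise models; ties are broken by the largest mean absolute
#' decision value among the tied classes, then lexicographically.
#'
#' @param X numeric matrix, one feature vector per row.
#' @param y character (or factor) class labels, >= 2 distinct classes.
#' @param spec a [kernel_spec()].
#' @param cost soft-margin cost parameter.
#' @param scale if `TRUE` (default), features are z-scored with training-set
#'   statistics stored in the model and applied at prediction time.
#' @return an object of class `maxmargin_multiclass`.
#' @export
train_multiclass <- function(X, y, spec = kernel_spec("linear"), cost = 1.5,
                             scale = TRUE) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("at least two classes are required")
  scaling <- NULL
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl <= 0] <- 1
    scaling <- list(center = ctr, scale = scl)
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    sel <- y %in% p
    yy <- ifelse(y[sel] == p[1], 1, -1)
    train_binary(X[sel, , drop = FALSE], yy, spec = spec, cost = cost)
  })
  names(models) <- vapply(pairs, function(p) pair_key(p[1], p[2]), character(1))
  structure(list(class_names = classes, pairwise_models = models,
                 scaling = scaling),
            class = "maxmargin_multiclass")
}

apply_scaling <- function(scaling, x) {
  if (is.null(scaling)) return(x)
  sweep(sweep(x, 2, scaling$center), 2, scaling$scale, "/")
}

#' Predict classes with a one-vs-one model
#'
#' @param model a `maxmargin_multiclass` from [train_multiclass()].
#' @param x a feature vector or matrix of feature vectors (rows).
#' @param margins if `TRUE`, also return the per-class mean absolute
#'   decision value used for tie-breaking.
#' @return character vector of class names (or a list with `label` and
#'   `margin` matrices when `margins = TRUE`).
#' @export
predict_multiclass <- function(model, x, margins = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  x <- apply_scaling(model$scaling, x)
  classes <- model$class_names
  votes <- matrix(0L, nrow(x), length(classes),
                  dimnames = list(NULL, classes))
  msum <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  mcnt <- 0L
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  for (p in pairs) {
    m <- model$pairwise_models[[pair_key(p[1], p[2])]]
    f <- decision_value(m, x)
    win <- ifelse(f >= 0, p[1], p[2])
    votes[cbind(seq_len(nrow(x)), match(win, classes))] <-
      votes[cbind(seq_len(nrow(x)), match(win, classes))] + 1L
    msum[, p[1]] <- msum[, p[1]] + abs(f)
    msum[, p[2]] <- msum[, p[2]] + abs(f)
  }
  mean_margin <- msum / (length(classes) - 1)
  label <- vapply(seq_len(nrow(x)), function(i) {
    v <- votes[i, ]
    top <- classes[v == max(v)]
    if (length(top) == 1) return(top)
    mm <- mean_margin[i, top]
    top <- top[mm == max(mm)]  # then lexicographic: classes are sorted
    top[1]
  }, character(1))
  if (margins) list(label = label, votes = votes, margin = mean_margin)
  else label
}

#' Cross-validation fold assignment
#'
#' Deterministic stratified k-fold splitter: within each class, samples are
#' dealt to folds in a seeded random order, so folds are balanced to within
#' one sample per class.
#'
#' @param y class labels (any vector).
#' @param k number of folds (>= 2).
#' @param seed RNG seed for the shuffle.
#' @return integer vector of fold indices in `1..k`, one per sample.
#' @export
cv_folds <- function(y, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  n <- length(y)
  if (k > n) stop("more folds than samples")
  folds <- integer(n)
  with_seed(mix_seed(seed, 97), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
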