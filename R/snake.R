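# Parametric closed contour (snake) with the classic internal energy
#   S(v) = 1/2 * integral( alpha |dv/ds|^2 + beta |d^2v/ds^2|^2 ) ds
# minimized together with an external force field by the greedy per-point
# window search (Williams-Shah). Contours are n x 2 matrices of (row, col)
# coordinates, 1-based, implicitly closed.

#' Snake parameters
#'
#' @param alpha continuity (tension) weight, >= 0.
#' @param beta curvature (rigidity) weight, >= 0.
#' @param search_radius half-width `d` of the per-point candidate window, in
#'   pixels; candidates are the `(2d+1)^2` integer offsets.
#' @param max_iter maximum number of greedy sweeps.
#' @param move_fraction_stop stop when fewer than this fraction of points
#'   moved in a sweep.
#' @param resample_spacing target arc-length spacing (px) used when the
#'   contour is periodically resampled during evolution.
#' @return an object of class `snake_params`.
#' @export
snake_params <- function(alpha = 1.44, beta = 1.58, search_radius = 8L,
                         max_iter = 200L, move_fraction_stop = 0.05,
                         resample_spacing = 5) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (search_radius < 1) stop("search_radius must be >= 1")
  if (move_fraction_stop <= 0 || move_fraction_stop >= 1)
    stop("move_fraction_stop must be in (0, 1)")
  structure(list(alpha = alpha, beta = beta,
                 search_radius = as.integer(search_radius),
                 max_iter = as.integer(max_iter),
                 move_fraction_stop = move_fraction_stop,
                 resample_spacing = resample_spacing),
            class = "snake_params")
}

as_contour <- function(points) {
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L || nrow(m) < 3L || anyNA(m))
    stop("a contour needs >= 3 finite (row, col) points")
  m
}

contour_perimeter <- function(points) {
  nxt <- rbind(points[-1, , drop = FALSE], points[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - points)^2)))
}

#' Resample a closed contour to equal arc-length spacing
#'
#' Vertices are placed uniformly along the closed polyline at approximately
#' `spacing` pixels apart; the number of output vertices is
#' `max(4, round(perimeter / spacing))`.
#'
#' @param points n x 2 matrix of (row, col) vertices, n >= 3.
#' @param spacing target spacing in pixels.
#' @return resampled contour matrix.
#' @export
resample_contour <- function(points, spacing) {
  pts <- as_contour(points)
  # drop consecutive duplicates
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  seg <- sqrt(rowSums((nxt - pts)^2))
  keep <- seg > 1e-12
  if (sum(keep) < 3) stop("contour has zero perimeter")
  pts <- pts[keep, , drop = FALSE]
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  seg <- sqrt(rowSums((nxt - pts)^2))
  per <- sum(seg)
  n_out <- max(4L, as.integer(round(per / spacing)))
  s_new <- per * (seq_len(n_out) - 1) / n_out
  cum <- c(0, cumsum(seg))
  idx <- findInterval(s_new, cum, rightmost.closed = TRUE)
  idx[idx > nrow(pts)] <- nrow(pts)
  t_loc <- (s_new - cum[idx]) / seg[idx]
  pts[idx, , drop = FALSE] + (nxt[idx, , drop = FALSE] - pts[idx, , drop = FALSE]) * t_loc
}

# Bilinear interpolation of a matrix at real-valued (row, col) positions,
# clamped to the valid domain.
bilinear <- function(mat, r, c) {
  n <- nrow(mat); m <- ncol(mat)
  r <- pmin(pmax(r, 1), n)
  c <- pmin(pmax(c, 1), m)
  r0 <- pmin(floor(r), n - 1L); c0 <- pmin(floor(c), m - 1L)
  fr <- r - r0; fc <- c - c0
  mat[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mat[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    mat[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    mat[cbind(r0 + 1, c0 + 1)] * fr * fc
}

minmax_norm <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 1e-300) return(rep(0, length(v)))
  (v - lo) / (hi - lo)
}

#' One greedy sweep of the snake
#'
#' Each point, visited in order, is moved to the candidate position (within
#' the `(2d+1)^2` integer-offset window) minimizing
#' `alpha * continuity + beta * curvature + image`, where each term is
#' min-max normalized over the window. The continuity term is
#' `|dbar - ||v_i - v_{i-1}|||` with `dbar` the mean point spacing at the
#' start of the sweep; the curvature term is `||v_{i-1} - 2 v_i + v_{i+1}||^2`;
#' the image term is the external energy interpolated at the candidate.
#' Ties go to the smallest offset magnitude, then row-major offset order, so
#' a uniform window leaves the point in place.
#'
#' @param contour n x 2 matrix of (row, col) points.
#' @param field a `force_field` from [compose_external_energy()], or a plain
#'   energy matrix.
#' @param params a [snake_params()].
#' @return list with `contour` (updated matrix) and `moved` (number of
#'   points that changed position).
#' @export
greedy_step <- function(contour, field, params = snake_params()) {
  pts <- as_contour(contour)
  energy <- if (inherits(field, "force_field")) field$energy else field
  n <- nrow(pts)
  d <- params$search_radius
  nr <- nrow(energy); nc <- ncol(energy)
  # clamp so the whole window stays in bounds
  pts[, 1] <- pmin(pmax(pts[, 1], 1 + d), nr - d)
  pts[, 2] <- pmin(pmax(pts[, 2], 1 + d), nc - d)
  off <- as.matrix(expand.grid(dr = -d:d, dc = -d:d))
  # row-major candidate order with (0,0) reachable: order by magnitude then
  # row-major for tie-breaking
  omag <- off[, 1]^2 + off[, 2]^2
  ord <- order(omag, off[, 1], off[, 2])
  off <- off[ord, , drop = FALSE]
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  seg <- sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2))
  dbar <- mean(seg)
  moved <- 0L
  for (i in seq_len(n)) {
    cand_r <- pts[i, 1] + off[, 1]
    cand_c <- pts[i, 2] + off[, 2]
    p_prev <- pts[prv[i], ]
    p_next <- pts[nxt[i], ]
    cont <- abs(dbar - sqrt((cand_r - p_prev[1])^2 + (cand_c - p_prev[2])^2))
    curv <- (p_prev[1] - 2 * cand_r + p_next[1])^2 +
            (p_prev[2] - 2 * cand_c + p_next[2])^2
    img <- bilinear(energy, cand_r, cand_c)
    total <- params$alpha * minmax_norm(cont) +
             params$beta * minmax_norm(curv) +
             minmax_norm(img)
    best <- which(total <= min(total) + 1e-12)[1]  # offsets pre-sorted for ties
    if (off[best, 1] != 0 || off[best, 2] != 0) {
      pts[i, ] <- c(cand_r[best], cand_c[best])
      moved <- moved + 1L
    }
  }
  list(contour = pts, moved = moved)
}

#' Evolve a snake to convergence
#'
#' Repeats [greedy_step()] until fewer than
#' `move_fraction_stop * n_points` points move in a sweep or `max_iter`
#' sweeps have run. The contour is resampled to uniform spacing every 10
#' sweeps. Deterministic given its inputs.
#'
#' @param initial initial contour, n x 2 matrix of (row, col) points.
#' @inheritParams greedy_step
#' @return the final contour matrix.
#' @export
evolve <- function(initial, field, params = snake_params()) {
  pts <- resample_contour(as_contour(initial), params$resample_spacing)
  for (it in seq_len(params$max_iter)) {
    st <- greedy_step(pts, field, params)
    pts <- st$contour
    if (st$moved < params$move_fraction_stop * nrow(pts)) break
    if (it %% 10L == 0L)
      pts <- resample_contour(pts, params$resample_spacing)
  }
  pts
}

#' Rasterize a closed contour to a binary mask
#'
#' A pixel is foreground when its center lies strictly inside the closed
#' polygon under the even-odd rule, or exactly on the polygon boundary.
#'
#' @param contour n x 2 matrix of (row, col) vertices, implicitly closed.
#' @param image_shape integer vector `(n_rows, n_cols)`.
#' @return logical matrix of the given shape.
#' @export
contour_to_mask <- function(contour, image_shape) {
  pts <- as_contour(contour)
  nr <- image_shape[1]; nc <- image_shape[2]
  mask <- matrix(FALSE, nr, nc)
  ys <- pts[, 1]; xs <- pts[, 2]
  yn <- c(ys[-1], ys[1]); xn <- c(xs[-1], xs[1])
  # even-odd scanline fill (horizontal edges carry no crossings)
  rmin <- max(1L, floor(min(ys))); rmax <- min(nr, ceiling(max(ys)))
  if (rmin > rmax) return(mask)
  nonh <- which(ys != yn)
  for (r in rmin:rmax) {
    crossing <- nonh[(ys[nonh] <= r & yn[nonh] > r) |
                     (yn[nonh] <= r & ys[nonh] > r)]
    if (length(crossing)) {
      xc <- xs[crossing] +
        (r - ys[crossing]) * (xn[crossing] - xs[crossing]) /
        (yn[crossing] - ys[crossing])
      xc <- sort(xc)
      inside <- findInterval(seq_len(nc), xc) %% 2 == 1
      mask[r, inside] <- TRUE
    }
  }
  # include pixel centers lying exactly on an edge segment
  tol <- 1e-9
  for (k in seq_len(nrow(pts))) {
    y1 <- ys[k]; x1 <- xs[k]; y2 <- yn[k]; x2 <- xn[k]
    rr <- max(1L, floor(min(y1, y2) - tol)):min(nr, ceiling(max(y1, y2) + tol))
    cc <- max(1L, floor(min(x1, x2) - tol)):min(nc, ceiling(max(x1, x2) + tol))
    if (length(rr) < 1 || length(cc) < 1) next
    g <- expand.grid(r = rr, c = cc)
    vy <- y2 - y1; vx <- x2 - x1
    len2 <- vy^2 + vx^2
    if (len2 < tol) next
    t_ <- pmin(pmax(((g$r - y1) * vy + (g$c - x1) * vx) / len2, 0), 1)
    dist2 <- (g$r - (y1 + t_ * vy))^2 + (g$c - (x1 + t_ * vx))^2
    on <- dist2 <= tol
    if (any(on)) mask[cbind(g$r[on], g$c[on])] <- TRUE
  }
  mask
}

#' Trace the boundary contour of a binary mask
#'
#' Returns the outer contour of the largest connected foreground component,
#' as traced pixel coordinates.
#'
#' @param mask logical or 0/1 matrix.
#' @return n x 2 matrix of (row, col) boundary points.
#' @export
mask_to_contour <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) stop("mask is empty")
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  oc <- EBImage::ocontour(EBImage::Image(lab == biggest))[[1]]
  # ocontour is 0-based in matrix (dim1, dim2) order
  cbind(oc[, 1] + 1, oc[, 2] + 1)
}
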