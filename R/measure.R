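# Overlap, area and classification metrics.

#' Jaccard overlap of two binary masks
#'
#' `|a & b| / |a | b|`. Two empty masks are identical shapes and score 1.
#'
#' @param a,b logical (or 0/1) matrices of the same shape.
#' @return overlap in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks differ in shape")
  a <- a > 0; b <- b > 0
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Area of a binary mask
#'
#' @param mask logical (or 0/1) matrix.
#' @param cal optional [calibration()]; when given, the physical area is
#'   `pixels * microns_per_pixel^2`.
#' @return list with `pixels` (count) and `physical` (square microns, or
#'   `NA` when uncalibrated).
#' @export
area <- function(mask, cal = NULL) {
  px <- sum(mask > 0)
  phys <- if (is.null(cal)) NA_real_ else px * cal$microns_per_pixel^2
  list(pixels = px, physical = phys)
}

#' Compare the areas of two masks
#'
#' @param a,b logical matrices.
#' @param cal a [calibration()].
#' @return list with `difference` (area(a) - area(b), square microns) and
#'   `ratio` (area(a)/area(b); `NA` when `b` is empty).
#' @export
compare_areas <- function(a, b, cal) {
  aa <- area(a, cal); ab <- area(b, cal)
  list(difference = aa$physical - ab$physical,
       ratio = if (ab$pixels == 0) NA_real_ else aa$physical / ab$physical)
}

#' Confusion-matrix metrics
#'
#' Per-class precision and recall and overall accuracy, in percent. Rows of
#' the matrix are predicted classes, columns are true classes; precision of
#' class k is `100 * cm[k, k] / rowsum_k`, recall is
#' `100 * cm[k, k] / colsum_k`. A zero row or column yields `NA` for the
#' corresponding metric.
#'
#' @param cm square numeric matrix of counts (optionally with dimnames
#'   giving the class names).
#' @return list with `precision`, `recall` (named numeric vectors, percent)
#'   and `accuracy` (percent).
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be nonnegative")
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is all-zero")
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  dg <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  precision <- ifelse(rs > 0, 100 * dg / rs, NA_real_)
  recall <- ifelse(cs > 0, 100 * dg / cs, NA_real_)
  names(precision) <- names(recall) <- classes
  list(precision = precision, recall = recall,
       accuracy = 100 * sum(dg) / total)
}
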