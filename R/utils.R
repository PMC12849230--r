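`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lo = -Inf, hi = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_named(field, "must be a single finite number")
  if (x < lo || x > hi)
    stop_named(field, sprintf("must be in [%s, %s]", lo, hi))
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_named(field, "must be a whole number")
  invisible(x)
}

#' Z-score the rows of a matrix
#'
#' Each row (region time series) is centred and scaled to unit standard
#' deviation. Constant rows are mapped to all-zero rows rather than NaN.
#'
#' @param x numeric matrix (regions x time points).
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1L, sd)
  out <- (x - m) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Area under the ROC curve from scores and binary labels
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive receives a higher score than a randomly chosen negative.
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector, same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
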