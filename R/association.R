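#' Overall F-test of fingerprints against a behavioural score
#'
#' Ordinary least squares regression of the score on the fingerprint
#' coordinates (plus intercept), with the overall F-test of the null that
#' all fingerprint coefficients are zero. Collinear fingerprint columns
#' are dropped with a warning.
#'
#' @param fingerprints subjects x dim matrix.
#' @param scores numeric vector, one score per subject (rows aligned).
#' @return object of class `bfp_ftest`: list with `F`, `df1`, `df2`, `p`,
#'   `r_squared`, `n`, `dropped` (collinear columns removed).
#' @export
fingerprint_regression <- function(fingerprints, scores) {
  X <- as.matrix(fingerprints)
  y <- as.numeric(scores)
  if (nrow(X) != length(y)) stop("fingerprints and scores differ in length")
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("non-finite values in the regression inputs")
  if (nrow(X) <= ncol(X) + 1L)
    stop("regression needs more subjects than fingerprint dimensions + 1")
  fit <- lm(y ~ X)
  dropped <- sum(is.na(coef(fit)))
  if (dropped > 0L)
    warning(sprintf("dropped %d collinear fingerprint column(s)", dropped))
  sm <- summary(fit)
  fs <- sm$fstatistic
  out <- list(F = unname(fs["value"]),
              df1 = unname(fs["numdf"]),
              df2 = unname(fs["dendf"]),
              p = unname(pf(fs["value"], fs["numdf"], fs["dendf"],
                            lower.tail = FALSE)),
              r_squared = sm$r.squared,
              n = nrow(X),
              dropped = dropped)
  class(out) <- "bfp_ftest"
  out
}

#' @export
print.bfp_ftest <- function(x, ...) {
  cat(sprintf("Fingerprint-score regression: F(%d, %d) = %.3f, p = %.4g (R^2 = %.3f, n = %d)\n",
              x$df1, x$df2, x$F, x$p, x$r_squared, x$n))
  invisible(x)
}

#' Pairwise fingerprint distances labelled by kinship
#'
#' Enumerates all cross-subject pairs, computes the cosine distance
#' between their fingerprints, and labels each pair related when its
#' kinship coefficient exceeds `pi_threshold` (first-degree relatives).
#'
#' @param fingerprints subjects x dim matrix with subject ids as rownames.
#' @param kinship data.frame with columns `id_1`, `id_2`, `pi_hat`.
#' @param pi_threshold relatedness cutoff on `pi_hat` (default 0.5).
#' @return data.frame with `id_1`, `id_2`, `distance`, `related`.
#' @export
fingerprint_pair_distances <- function(fingerprints, kinship,
                                       pi_threshold = 0.5) {
  subj <- rownames(fingerprints)
  D <- cosine_distance_matrix(fingerprints, fingerprints)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  out <- data.frame(id_1 = subj[idx[, 1]], id_2 = subj[idx[, 2]],
                    distance = D[idx], stringsAsFactors = FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rel <- kinship[kinship$pi_hat > pi_threshold, , drop = FALSE]
  out$related <- key(out$id_1, out$id_2) %in% key(rel$id_1, rel$id_2)
  out
}

#' Two-sample t-test of fingerprint distances by kinship
#'
#' Pooled-variance two-sample t-test (df = n1 + n2 - 2) comparing
#' fingerprint distances of genetically related pairs against unrelated
#' pairs. A negative t indicates that related pairs have the more similar
#' fingerprints.
#'
#' @param pairs data.frame from [fingerprint_pair_distances()] (columns
#'   `distance`, `related`).
#' @return list with `t`, `df`, `p`, `mean_related`, `mean_unrelated`,
#'   `n_related`, `n_unrelated`.
#' @export
kinship_distance_test <- function(pairs) {
  rel <- pairs$distance[pairs$related]
  unrel <- pairs$distance[!pairs$related]
  if (length(rel) < 2L || length(unrel) < 2L)
    stop("both kinship groups need at least 2 pairs")
  tt <- t.test(rel, unrel, var.equal = TRUE)
  list(t = unname(tt$statistic),
       df = unname(tt$parameter),
       p = tt$p.value,
       mean_related = mean(rel),
       mean_unrelated = mean(unrel),
       n_related = length(rel),
       n_unrelated = length(unrel))
}
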