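#' Database-versus-target individual identification
#'
#' Each target fingerprint is assigned the identity of the database
#' fingerprint at minimal cosine distance. Identification is performed
#' with replacement: every target may match any database subject
#' regardless of previous matches. Exact distance ties break
#' deterministically toward the lowest database index and are reported.
#'
#' @param targets matrix of target fingerprints (subjects x dim, rownames
#'   = true subject ids).
#' @param database matrix of database fingerprints (one row per subject,
#'   rownames = subject ids).
#' @return data.frame with columns `target`, `predicted`, `distance`,
#'   `tie` (logical), one row per target.
#' @export
identify_subjects <- function(targets, database) {
  if (is.null(dim(database)) || nrow(database) == 0L)
    stop("empty fingerprint database")
  if (ncol(targets) != ncol(database))
    stop("fingerprint dimensions differ between targets and database")
  if (anyDuplicated(rownames(database)))
    stop("database must hold exactly one fingerprint per subject")
  D <- cosine_distance_matrix(targets, database)
  best <- apply(D, 1L, which.min)        # which.min: lowest index on ties
  tie <- vapply(seq_len(nrow(D)), function(i)
    sum(D[i, ] <= D[i, best[i]] + 1e-15) > 1L, logical(1))
  if (any(tie))
    message(sprintf("%d target(s) had exact distance ties; matched to the lowest database index", sum(tie)))
  data.frame(target = rownames(targets),
             predicted = rownames(database)[best],
             distance = D[cbind(seq_len(nrow(D)), best)],
             tie = tie,
             stringsAsFactors = FALSE)
}

#' Identification success rate
#'
#' Fraction of targets whose predicted identity equals the true identity.
#'
#' @param predictions data.frame from [identify_subjects()] (columns
#'   `target` and `predicted`).
#' @return SR in \[0, 1\].
#' @export
success_rate <- function(predictions) {
  mean(predictions$predicted == predictions$target)
}

#' Intra/inter-class distance ratio (CR)
#'
#' Mean same-subject (database vs target) cosine distance divided by the
#' mean different-subject distance. Lower values indicate better
#' separation.
#'
#' @param database,targets fingerprint matrices covering the same
#'   subjects (matched by rowname).
#' @return the ratio CR.
#' @export
distance_ratio <- function(database, targets) {
  subj <- rownames(database)
  if (length(subj) < 2L) stop("CR needs at least 2 subjects")
  if (!setequal(subj, rownames(targets)))
    stop("database and targets must cover the same subjects")
  targets <- targets[subj, , drop = FALSE]
  D <- cosine_distance_matrix(database, targets)
  intra <- mean(diag(D))
  inter <- mean(D[row(D) != col(D)])
  intra / inter
}

#' Silhouette coefficient under cosine distance
#'
#' Standard silhouette on the pooled fingerprints: for each sample,
#' `s = (b - a) / max(a, b)` where `a` is its mean distance to same-subject
#' samples and `b` the smallest mean distance to another subject's
#' samples; SC is the mean of `s`. Degenerate samples (0/0) score 0, and a
#' subject with a single sample contributes 0 with a warning.
#'
#' @param x matrix of fingerprints (samples x dim).
#' @param labels subject label per row.
#' @return SC in \[-1, 1\].
#' @export
silhouette_coef <- function(x, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("silhouette needs >= 2 subjects")
  D <- cosine_distance_matrix(x, x)
  n <- nrow(D)
  s <- numeric(n)
  singleton <- FALSE
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) == 0L) { singleton <- TRUE; s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  if (singleton)
    warning("subject(s) with a single sample contribute silhouette 0")
  mean(s)
}

#' Permutation test for identification success
#'
#' Holds the predictions fixed and relabels the target identities by
#' uniform random permutations, recomputing the SR each time. The p-value
#' uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @param predictions data.frame from [identify_subjects()].
#' @param n_permutations number of random permutations (>= 1).
#' @param seed RNG seed.
#' @return list with `observed` SR, `null_sr` (all permutation SRs),
#'   `max_null`, and `p_value`.
#' @export
permutation_test <- function(predictions, n_permutations = 10000L,
                             seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  set.seed(seed)
  obs <- success_rate(predictions)
  truth <- predictions$target
  pred <- predictions$predicted
  null_sr <- vapply(seq_len(n_permutations), function(i)
    mean(pred == sample(truth)), numeric(1))
  list(observed = obs,
       null_sr = null_sr,
       max_null = max(null_sr),
       p_value = (1 + sum(null_sr >= obs)) / (1 + n_permutations))
}

#' Full identification report for one database/target pairing
#'
#' Computes SR, CR and SC (silhouette over the union of both runs'
#' fingerprints) plus, optionally, the permutation null.
#'
#' @param database,targets fingerprint matrices covering the same
#'   subjects.
#' @param direction label describing which run served as database.
#' @param n_permutations permutations for the null SR distribution (0
#'   skips the test).
#' @param seed permutation seed.
#' @param strict error (rather than warn and intersect) when subject sets
#'   differ.
#' @return object of class `identification_report`.
#' @export
evaluate_identification <- function(database, targets,
                                    direction = "A->B",
                                    n_permutations = 0L, seed = 1L,
                                    strict = TRUE) {
  common <- intersect(rownames(database), rownames(targets))
  if (!setequal(rownames(database), rownames(targets))) {
    if (strict) stop("database and target subject sets differ")
    warning(sprintf("subject sets differ; restricting to the %d shared subjects",
                    length(common)))
  }
  database <- database[common, , drop = FALSE]
  targets <- targets[common, , drop = FALSE]
  pred <- identify_subjects(targets, database)
  pooled <- rbind(database, targets)
  rep <- list(SR = success_rate(pred),
              CR = distance_ratio(database, targets),
              SC = silhouette_coef(pooled, c(rownames(database),
                                             rownames(targets))),
              n = length(common),
              direction = direction,
              predictions = pred)
  if (n_permutations > 0L) {
    pt <- permutation_test(pred, n_permutations, seed)
    rep$null_sr <- pt$null_sr
    rep$max_null <- pt$max_null
    rep$p_value <- pt$p_value
  }
  structure(rep, class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("Identification report (%s, N = %d)\n", x$direction, x$n))
  cat(sprintf("  SR = %.3f   CR = %.3f   SC = %.3f\n", x$SR, x$CR, x$SC))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation null: max SR = %.3f, p = %.4g (%d permutations)\n",
                x$max_null, x$p_value, length(x$null_sr)))
  invisible(x)
}

#' Bidirectional identification
#'
#' Evaluates identification with run A as database and run B as targets,
#' then swaps the roles; both reports are retained since the two
#' directions can differ.
#'
#' @param fp_a,fp_b fingerprint matrices for the two runs.
#' @param labels length-2 labels naming the runs.
#' @inheritParams evaluate_identification
#' @return list of two `identification_report` objects.
#' @export
bidirectional_evaluate <- function(fp_a, fp_b, labels = c("A", "B"),
                                   n_permutations = 0L, seed = 1L,
                                   strict = TRUE) {
  list(forward = evaluate_identification(
         fp_a, fp_b, sprintf("%s->%s", labels[1], labels[2]),
         n_permutations, seed, strict),
       reverse = evaluate_identification(
         fp_b, fp_a, sprintf("%s->%s", labels[2], labels[1]),
         n_permutations, seed, strict))
}

#' Functional-connectome fingerprint features
#'
#' Vectorised upper triangle of the region-by-region Pearson correlation
#' matrix. Constant region series produce zero correlations with a
#' warning.
#'
#' @param x R x T run matrix.
#' @return numeric vector of length R(R-1)/2.
#' @export
connectome_features <- function(x) {
  s <- apply(x, 1L, sd)
  if (any(s == 0)) {
    warning(sprintf("%d constant region series; their correlations set to 0",
                    sum(s == 0)))
    FC <- suppressWarnings(cor(t(x)))
    FC[is.na(FC)] <- 0
  } else {
    FC <- cor(t(x))
  }
  FC[upper.tri(FC)]
}

#' Connectome-correlation identification baseline
#'
#' The classic fingerprinting protocol: each run is summarised by its
#' functional connectivity (upper-triangle Pearson correlations), and a
#' target is matched to the database entry with the highest Pearson
#' correlation between FC vectors. SR/CR/SC are computed on the
#' correlation distance `1 - r`.
#'
#' @param runs_db,runs_target named lists of R x T matrices (names =
#'   subject ids), covering the same subjects.
#' @param direction report label.
#' @return an `identification_report`.
#' @export
connectome_baseline <- function(runs_db, runs_target,
                                direction = "connectome A->B") {
  subj <- names(runs_db)
  if (!setequal(subj, names(runs_target)))
    stop("database and target runs must cover the same subjects")
  nf <- nrow(runs_db[[1]]) * (nrow(runs_db[[1]]) - 1L) / 2L
  feat_db <- t(vapply(runs_db, connectome_features, numeric(nf)))
  feat_tg <- t(vapply(runs_target[subj], connectome_features, numeric(nf)))
  # match by maximal Pearson correlation == minimal correlation distance
  Dcor <- 1 - cor(t(feat_tg), t(feat_db))
  best <- apply(Dcor, 1L, which.min)
  pred <- data.frame(target = subj, predicted = subj[best],
                     distance = Dcor[cbind(seq_along(subj), best)],
                     tie = FALSE, stringsAsFactors = FALSE)
  # row-centre so that cosine distance on features equals 1 - Pearson r
  pooled <- rbind(feat_db, feat_tg)
  pooled <- pooled - rowMeans(pooled)
  structure(list(SR = success_rate(pred),
                 CR = {
                   intra <- mean(diag(Dcor))
                   inter <- mean(Dcor[row(Dcor) != col(Dcor)])
                   intra / inter
                 },
                 SC = silhouette_coef(pooled, c(subj, subj)),
                 n = length(subj),
                 direction = direction,
                 predictions = pred),
            class = "identification_report")
}
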