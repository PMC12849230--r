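#' Attention-based BOLD token importance
#'
#' Quantifies each time point's contribution to the fingerprint as the
#' CLS-attention mass it receives: for token `t`, the attention weights
#' from every window's CLS query to `t` are summed over blocks, heads and
#' windows whose receptive field contains `t`, then divided by the number
#' of covering windows.
#'
#' @param model a `fingerprint_model`.
#' @param x R x T run matrix.
#' @param attention optionally, a stored attention record from
#'   [encode_run()] (with `record_attention = TRUE`) to reuse instead of a
#'   fresh forward pass.
#' @return numeric vector of length T, non-negative.
#' @export
token_importance <- function(model, x, attention = NULL) {
  if (is.null(attention)) {
    enc <- encode_run(x, model$params, model$encoder,
                      record_attention = TRUE)
    attention <- enc$attention
  }
  T <- ncol(x)
  imp <- numeric(T)
  cover <- numeric(T)
  first <- TRUE
  for (blk in attention) {
    for (win in blk) {
      idx <- win$rf_start:win$rf_end
      for (a_h in win$cls_attention) imp[idx] <- imp[idx] + a_h
      if (first) cover[idx] <- cover[idx] + 1
    }
    first <- FALSE
  }
  imp / pmax(cover, 1)
}

#' Random-forest region contribution weights
#'
#' Translates token-level importance into region-level importance: per
#' participant the `labeling_k` most and least important BOLD tokens are
#' labelled 1 and 0; the raw (z-scored) R-vectors at those time points,
#' pooled over participants, feed a random-forest classifier; the
#' normalised impurity importances are the region weights W.
#'
#' @param runs list of R x T run matrices (one per participant).
#' @param importances list of token-importance vectors matching `runs`.
#' @param labeling_k tokens labelled per extreme (default 5).
#' @param n_trees random-forest size.
#' @param seed forest seed.
#' @return named numeric vector W of length R, non-negative, summing to 1.
#' @export
region_contribution <- function(runs, importances, labeling_k = 5L,
                                n_trees = 500L, seed = 1L) {
  stopifnot(length(runs) == length(importances))
  feats <- list(); labs <- list()
  for (i in seq_along(runs)) {
    imp <- importances[[i]]
    T <- length(imp)
    if (T < 2L * labeling_k)
      stop("each run needs at least 2 * labeling_k tokens")
    ord <- order(imp)
    bottom <- ord[seq_len(labeling_k)]
    top <- ord[seq.int(T - labeling_k + 1L, T)]
    z <- zscore_rows(runs[[i]])
    feats[[i]] <- t(z[, c(top, bottom), drop = FALSE])
    labs[[i]] <- rep(c(1L, 0L), each = labeling_k)
  }
  Xf <- do.call(rbind, feats)
  y <- factor(unlist(labs))
  if (length(unique(y)) < 2L)
    stop("degenerate token labels: only one class present")
  colnames(Xf) <- sprintf("r%03d", seq_len(ncol(Xf)))
  set.seed(seed)
  rf <- randomForest::randomForest(Xf, y, ntree = n_trees,
                                   importance = FALSE)
  W <- rf$importance[, "MeanDecreaseGini"]
  W <- pmax(W, 0)
  if (sum(W) == 0) stop("all-zero forest importances")
  W / sum(W)
}

#' Network contrasts of region contributions
#'
#' Two-sample pooled-variance t-tests on the region weights W: each
#' network against all other regions, plus the higher-order association
#' networks (default-mode, frontoparietal, ventral attention) against the
#' primary visual and somatomotor networks. Degrees of freedom are
#' `n1 + n2 - 2`.
#'
#' @param W region weight vector.
#' @param networks network label per region.
#' @param higher,lower network labels defining the higher-vs-lower
#'   contrast.
#' @return data.frame with columns `contrast`, `n1`, `n2`, `df`, `t`, `p`.
#' @export
network_contrast <- function(W, networks,
                             higher = c("Default", "Frontoparietal",
                                        "VentralAttention"),
                             lower = c("Visual", "Somatomotor")) {
  stopifnot(length(W) == length(networks))
  networks <- as.character(networks)
  pooled_t <- function(x, y) {
    # two-sample pooled-variance t; degenerate (zero-variance) data give t = 0
    df <- length(x) + length(y) - 2L
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) / df
    if (sp2 <= .Machine$double.eps * max(abs(c(x, y, 1)))^2)
      return(list(statistic = 0, parameter = df, p.value = 1))
    tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    list(statistic = tval, parameter = df,
         p.value = 2 * pt(-abs(tval), df))
  }
  rows <- list()
  for (net in unique(networks)) {
    in_net <- networks == net
    if (sum(in_net) < 2L) {
      warning(sprintf("network %s has < 2 regions; skipped", net))
      next
    }
    tt <- pooled_t(W[in_net], W[!in_net])
    rows[[length(rows) + 1L]] <-
      data.frame(contrast = sprintf("%s_vs_rest", net),
                 n1 = sum(in_net), n2 = sum(!in_net),
                 df = unname(tt$parameter), t = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
  }
  hi <- networks %in% higher; lo <- networks %in% lower
  if (sum(hi) >= 2L && sum(lo) >= 2L) {
    tt <- pooled_t(W[hi], W[lo])
    rows[[length(rows) + 1L]] <-
      data.frame(contrast = "higher_order_vs_primary",
                 n1 = sum(hi), n2 = sum(lo),
                 df = unname(tt$parameter), t = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# precompute pair indices, bin assignment and bin summaries for D
variogram_structure <- function(D, n_bins = 10L, max_frac = 0.75) {
  idx <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[upper.tri(D)]
  keep <- d <= quantile(d, max_frac)
  idx <- idx[keep, , drop = FALSE]
  d <- d[keep]
  br <- quantile(d, probs = seq(0, 1, length.out = n_bins + 1L))
  br[1] <- -Inf
  bin <- cut(d, unique(br), labels = FALSE)
  list(i = idx[, 1], j = idx[, 2], bin = bin,
       h = as.numeric(rowsum(d, bin) / tabulate(bin)),
       counts = tabulate(bin))
}

variogram_gamma <- function(values, vs) {
  g <- 0.5 * (values[vs$i] - values[vs$j])^2
  as.numeric(rowsum(g, vs$bin)) / vs$counts
}

#' Empirical variogram of a regional map
#'
#' Half squared differences `0.5 * (y_i - y_j)^2` averaged within
#' distance bins (equal-count bins up to the `max_frac` quantile of
#' pairwise distances).
#'
#' @param values regional map values.
#' @param D pairwise distance matrix.
#' @param n_bins number of distance bins.
#' @param max_frac quantile of distances up to which pairs are used.
#' @return data.frame with `h` (mean bin distance) and `gamma`.
#' @export
empirical_variogram <- function(values, D, n_bins = 10L, max_frac = 0.75) {
  vs <- variogram_structure(D, n_bins, max_frac)
  data.frame(h = vs$h, gamma = variogram_gamma(values, vs))
}

#' Variogram-matching spatial surrogate maps
#'
#' Generates null maps that preserve both the value distribution and the
#' spatial autocorrelation of the input: each surrogate is a random
#' permutation of the map smoothed with a distance-decaying Gaussian
#' kernel, rank-remapped back to the original value multiset, with the
#' kernel scale and a white-noise admixture chosen (per surrogate) to
#' minimise the worst-bin relative discrepancy to the original empirical
#' variogram. A zero-smoothing candidate is always included, so maps
#' without spatial structure fall back to plain permutations.
#'
#' @param values regional map (length R >= 10).
#' @param D pairwise region distance matrix.
#' @param n_surrogates number of surrogate maps (>= 100 recommended for
#'   inference).
#' @param n_scales number of candidate kernel scales (distance quantiles).
#' @param noise_mix candidate white-noise admixture weights controlling
#'   short-range roughness.
#' @param n_bins variogram bins used for the fit.
#' @param seed RNG seed.
#' @return R x n_surrogates matrix; every column has exactly the original
#'   value multiset.
#' @export
variogram_surrogates <- function(values, D, n_surrogates = 1000L,
                                 n_scales = 8L,
                                 noise_mix = c(0, 0.05, 0.1, 0.2, 0.3, 0.5),
                                 n_bins = 10L, seed = 1L) {
  R <- length(values)
  if (R < 10L) stop("variogram surrogates need at least 10 regions")
  stopifnot(nrow(D) == R, ncol(D) == R)
  set.seed(seed)
  vs <- variogram_structure(D, n_bins)
  g0 <- pmax(variogram_gamma(values, vs), 1e-12)
  sorted <- sort(values)
  dq <- quantile(D[upper.tri(D)],
                 probs = seq(0.03, 0.6, length.out = n_scales))
  kernels <- lapply(dq, function(delta) {
    Wk <- exp(-D^2 / (2 * delta^2))
    Wk / rowSums(Wk)
  })
  relerr <- function(y) max(abs(variogram_gamma(y, vs) - g0) / g0)
  out <- matrix(0, R, n_surrogates)
  for (k in seq_len(n_surrogates)) {
    perm <- sample(values)
    rough <- rnorm(R)
    best <- perm
    best_sse <- relerr(perm)
    for (Wk in kernels) {
      sm <- as.vector(Wk %*% perm)
      sm <- (sm - mean(sm)) / max(sd(sm), 1e-12)
      for (lam in noise_mix) {
        cand <- sorted[rank((1 - lam) * sm + lam * rough,
                            ties.method = "first")]
        sse <- relerr(cand)
        if (sse < best_sse) { best <- cand; best_sse <- sse }
      }
    }
    out[, k] <- best
  }
  out
}

#' Spatial correlation with a surrogate-based permutation p-value
#'
#' Pearson correlation between a region weight map and an annotation map,
#' with significance assessed against surrogate maps that preserve the
#' annotation map's spatial autocorrelation.
#'
#' @param W region weight vector.
#' @param map annotation map on the same atlas.
#' @param surrogates R x n matrix of surrogate versions of `map` (e.g.
#'   from [variogram_surrogates()]).
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   association only, as in the gene screen).
#' @return list with `r`, `p`, `n_surrogates`.
#' @export
map_association <- function(W, map, surrogates,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (sd(W) == 0 || sd(map) == 0)
    stop("map association undefined for zero-variance inputs")
  r <- cor(W, map)
  r_null <- as.vector(cor(W, surrogates))
  n <- length(r_null)
  p <- if (alternative == "two.sided") {
    (1 + sum(abs(r_null) >= abs(r))) / (1 + n)
  } else {
    (1 + sum(r_null >= r)) / (1 + n)
  }
  list(r = r, p = p, n_surrogates = n)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment of p-values with significance calls at level `q`.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param q FDR level (0.05 for annotation maps; the lenient 0.1 is used
#'   for the gene screen).
#' @return data.frame with `p`, `p_adj`, `significant`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, p_adj = adj, significant = adj < q)
}

#' Screen gene-expression maps against region contributions
#'
#' Correlates each gene's regional expression profile with the region
#' weights W, computes one-sided (positively correlated) surrogate
#' p-values against spatial-autocorrelation-preserving surrogates of W,
#' and applies BH correction at the lenient level `q`.
#'
#' @param expression genes x R matrix (rownames = gene ids) aligned to the
#'   atlas; genes with missing regions are dropped (count reported).
#' @param W region weight vector.
#' @param surrogates surrogate maps of `W` (R x n matrix).
#' @param q FDR level (default 0.1).
#' @return data.frame with `gene`, `r`, `p`, `p_adj`, `selected`, sorted
#'   by decreasing r.
#' @export
gene_map_screen <- function(expression, W, surrogates, q = 0.1) {
  if (ncol(expression) != length(W))
    stop("expression columns must align with the atlas regions")
  ok <- complete.cases(expression)
  if (any(!ok))
    message(sprintf("dropped %d gene(s) with missing regional values",
                    sum(!ok)))
  expression <- expression[ok, , drop = FALSE]
  res <- lapply(seq_len(nrow(expression)), function(i)
    map_association(as.numeric(expression[i, ]), W, surrogates,
                    alternative = "greater"))
  # one-sided against surrogates of W: r_null = cor(gene, W_surr)
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  adj <- fdr_correct(p, q)
  out <- data.frame(gene = rownames(expression), r = r, p = p,
                    p_adj = adj$p_adj, selected = adj$significant,
                    stringsAsFactors = FALSE)
  out[order(-out$r), ]
}
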