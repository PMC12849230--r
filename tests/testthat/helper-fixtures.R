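# Shared fixtures, built in code at test time.

tiny_encoder <- function(n_regions = 5L, seed = 3L, dropout = 0) {
  encoder_config(n_regions = n_regions, embed_dim = 8L, window_length = 6L,
                 window_stride = 3L, fringe_length = 2L, n_blocks = 2L,
                 n_heads = 2L, mlp_hidden = 10L, dropout = dropout,
                 seed = seed)
}

desk_sim <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

small_sim <- function(seed = 1L, kinship_pairs = 2L, ...) {
  # reduced cohort for fast structural tests
  sim_config(n_subjects = 8L, n_regions = 20L, n_timepoints = 60L,
             kinship_pairs = kinship_pairs, seed = seed, ...)
}

random_run <- function(R = 5L, T = 40L, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(R * T), R, T)
}

# memoised store for expensive trained models shared across test files
.bfp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .bfp_cache))
    assign(key, force(expr), envir = .bfp_cache)
  get(key, envir = .bfp_cache)
}

# desk-scale cohorts and trained models shared by the acceptance checks
acceptance_cohort <- function(seed) {
  cached(sprintf("acc_cohort_%d", seed),
         simulate_cohort(sim_config(seed = seed)))
}

acceptance_model <- function(seed) {
  cached(sprintf("acc_model_%d", seed), {
    co <- acceptance_cohort(seed)
    fit_fingerprint_model(co,
                          training = training_config(epochs = 10,
                                                     seed = seed))
  })
}

small_fit <- function() {
  cached("small_fit", {
    co <- cached("small_cohort", simulate_cohort(small_sim()))
    enc <- encoder_config(n_regions = 20, embed_dim = 8,
                          window_length = 10, window_stride = 5,
                          fringe_length = 5, n_blocks = 1, n_heads = 2,
                          seed = 1)
    fit_fingerprint_model(co, encoder = enc,
                          training = training_config(epochs = 5,
                                                     batch_size = 4,
                                                     seed = 1))
  })
}

# brute-force metric oracles, independent of the package implementation ----

bf_cosdist <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))

bf_distmat <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      out[i, j] <- bf_cosdist(A[i, ], B[j, ])
  out
}

bf_sr <- function(db, tg) {
  D <- bf_distmat(tg, db)
  correct <- 0
  for (i in seq_len(nrow(tg))) {
    j <- which.min(D[i, ])
    if (rownames(db)[j] == rownames(tg)[i]) correct <- correct + 1
  }
  correct / nrow(tg)
}

bf_cr <- function(db, tg) {
  tg <- tg[rownames(db), , drop = FALSE]
  D <- bf_distmat(db, tg)
  intra <- inter <- c()
  for (i in seq_len(nrow(db)))
    for (j in seq_len(nrow(tg))) {
      if (i == j) intra <- c(intra, D[i, j]) else inter <- c(inter, D[i, j])
    }
  mean(intra) / mean(inter)
}

bf_silhouette <- function(X, labels) {
  D <- bf_distmat(X, X)
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == l]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
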