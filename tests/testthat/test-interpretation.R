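# token/region attribution, network contrasts, surrogate maps, FDR

test_that("token importance is recomputable from a stored attention record", {
  cfg <- tiny_encoder()
  params <- init_encoder(cfg)
  model <- list(params = params, encoder = cfg)
  x <- random_run(5, 30, seed = 9)
  fresh <- token_importance(model, x)
  enc <- encode_run(x, params, cfg, record_attention = TRUE)
  stored <- token_importance(model, x, attention = enc$attention)
  expect_equal(fresh, stored, tolerance = 1e-12)
  expect_length(fresh, 30)
  expect_true(all(fresh >= 0))
  expect_true(all(is.finite(fresh)))
})

test_that("uniform attention yields a constant importance vector", {
  # fringe 0 so every window has the same field; the per-token average over
  # covering windows then cancels the unequal edge coverage exactly
  cfg <- encoder_config(n_regions = 5, embed_dim = 8, window_length = 6,
                        window_stride = 3, fringe_length = 0, n_blocks = 2,
                        n_heads = 2, dropout = 0, seed = 1)
  ws <- window_slices(24, cfg$window_length, cfg$window_stride)
  attn <- lapply(seq_len(cfg$n_blocks), function(b)
    lapply(seq_len(nrow(ws)), function(f) {
      nk <- ws$stop[f] - ws$start[f]
      list(cls_attention = replicate(cfg$n_heads,
                                     rep(1 / nk, nk), simplify = FALSE),
           rf_start = ws$start[f] + 1, rf_end = ws$stop[f],
           core_start = ws$start[f] + 1, core_end = ws$stop[f])
    }))
  model <- list(params = NULL, encoder = cfg)
  imp <- token_importance(model, matrix(0, 5, 24), attention = attn)
  expect_equal(max(imp) - min(imp), 0, tolerance = 1e-12)
})

test_that("a single token receiving all CLS attention is the argmax", {
  cfg <- tiny_encoder()
  T <- 24
  ws <- window_slices(T, cfg$window_length, cfg$window_stride)
  target <- 11L
  attn <- lapply(seq_len(cfg$n_blocks), function(b)
    lapply(seq_len(nrow(ws)), function(f) {
      rf_start <- max(1, ws$start[f] + 1 - cfg$fringe_length)
      rf_end <- min(T, ws$stop[f] + cfg$fringe_length)
      nk <- rf_end - rf_start + 1
      w <- rep(1e-6, nk); w <- w / sum(w)
      if (target >= rf_start && target <= rf_end) {
        w <- rep(0, nk); w[target - rf_start + 1] <- 1
      }
      list(cls_attention = replicate(cfg$n_heads, w, simplify = FALSE),
           rf_start = rf_start, rf_end = rf_end,
           core_start = ws$start[f] + 1, core_end = ws$stop[f])
    }))
  model <- list(params = NULL, encoder = cfg)
  imp <- token_importance(model, matrix(0, 5, T), attention = attn)
  expect_equal(which.max(imp), target)
})

test_that("region contribution concentrates on the informative region", {
  set.seed(4)
  # region 1 alone separates the labelled extremes perfectly
  runs <- lapply(1:6, function(i) {
    x <- matrix(rnorm(8 * 40), 8, 40)
    x[1, 1:10] <- x[1, 1:10] + 6     # high-importance tokens will sit here
    x
  })
  imps <- lapply(runs, function(x) {
    imp <- runif(40, 0, 0.1)
    imp[1:10] <- 1 + runif(10)       # top tokens = the shifted ones
    imp
  })
  W <- region_contribution(runs, imps, labeling_k = 5, seed = 2)
  expect_equal(sum(W), 1, tolerance = 1e-9)
  expect_true(all(W >= 0))
  expect_gt(W[1], max(W[-1]))
})

test_that("shuffled labels flatten the region contribution profile", {
  set.seed(8)
  runs <- lapply(1:6, function(i) {
    x <- matrix(rnorm(8 * 40), 8, 40)
    x[1, 1:10] <- x[1, 1:10] + 6
    x
  })
  informative <- lapply(runs, function(x) {
    imp <- runif(40, 0, 0.1); imp[1:10] <- 1 + runif(10); imp
  })
  W_informative <- region_contribution(runs, informative, seed = 1)
  maxW <- vapply(1:10, function(s) {
    shuffled <- lapply(informative, sample)
    max(region_contribution(runs, shuffled, seed = s))
  }, numeric(1))
  # under shuffling no region dominates: profile stays near uniform (1/8)
  expect_lt(mean(maxW), W_informative[1])
  expect_lt(mean(maxW), 2.5 / 8)
})

test_that("region contributions are stable across training intervals", {
  # models trained on within-session pairs vs 4-year-interval pairs should
  # attribute the fingerprint to similar regions
  rs <- vapply(1:5, function(seed) {
    co <- acceptance_cohort(seed)
    m_within <- acceptance_model(seed)
    m_4y <- cached(sprintf("acc_model4y_%d", seed),
                   fit_fingerprint_model(co,
                                         session_pair = c("baseline", "year4"),
                                         run_pair = c(1L, 1L),
                                         training = training_config(
                                           epochs = 10, seed = seed)))
    runs <- session_runs(co, "baseline", 1)
    W1 <- region_contribution(runs,
                              lapply(runs, function(x)
                                token_importance(m_within, x)),
                              seed = seed)
    W2 <- region_contribution(runs,
                              lapply(runs, function(x)
                                token_importance(m_4y, x)),
                              seed = seed)
    cor(W1, W2)
  }, numeric(1))
  expect_true(all(rs > 0.5))
})

test_that("network contrasts match the closed-form two-sample t", {
  networks <- rep(c("A", "B"), each = 3)
  W <- c(1, 2, 3, 1, 2, 3) / 12
  out <- network_contrast(W, networks, higher = "A", lower = "B")
  expect_equal(out$t[out$contrast == "A_vs_rest"], 0, tolerance = 1e-12)
  # shift network A by delta on equal variance groups
  delta <- 0.05
  W2 <- W + delta * (networks == "A")
  out2 <- network_contrast(W2, networks, higher = "A", lower = "B")
  n1 <- 3; n2 <- 3
  sp <- sqrt(((n1 - 1) * var(W2[1:3]) + (n2 - 1) * var(W2[4:6])) /
               (n1 + n2 - 2))
  t_hand <- (mean(W2[1:3]) - mean(W2[4:6])) / (sp * sqrt(1 / n1 + 1 / n2))
  expect_equal(out2$t[out2$contrast == "A_vs_rest"], t_hand,
               tolerance = 1e-12)
  expect_equal(out2$df[out2$contrast == "A_vs_rest"], 4)
  # constant W gives t = 0 everywhere
  out3 <- network_contrast(rep(0.1, 6), networks, higher = "A", lower = "B")
  expect_true(all(out3$t == 0))
})

test_that("one-network-vs-rest degrees of freedom follow n1 + n2 - 2", {
  at <- cohort_atlas(219)
  W <- runif(219); W <- W / sum(W)
  out <- network_contrast(W, at$network_label)
  expect_true(all(out$df[grepl("_vs_rest", out$contrast)] == 217))
})

test_that("surrogates keep the value multiset and the variogram shape", {
  geo <- region_geometry(60)
  D <- region_distances(geo)
  map <- geo$z + 0.1 * sin(3 * geo$x)      # smooth spatial gradient
  sur <- variogram_surrogates(map, D, n_surrogates = 40, seed = 3)
  expect_equal(dim(sur), c(60, 40))
  for (k in 1:40)
    expect_equal(sort(sur[, k]), sort(map), tolerance = 1e-12)
  v0 <- empirical_variogram(map, D)
  relerr <- vapply(1:40, function(k) {
    vk <- empirical_variogram(sur[, k], D)
    abs(vk$gamma - v0$gamma) / pmax(v0$gamma, 1e-12)
  }, numeric(nrow(v0)))
  # per-bin median relative error across surrogates stays within 25%
  expect_true(all(apply(relerr, 1, median) < 0.25))
  expect_error(variogram_surrogates(rnorm(5), D[1:5, 1:5]), "at least 10")
})

test_that("map association recovers exact and antipodal matches", {
  geo <- region_geometry(40)
  D <- region_distances(geo)
  W <- geo$z + rnorm(40, sd = 0.1)
  sur <- variogram_surrogates(W, D, n_surrogates = 99, seed = 2)
  self <- map_association(W, W, sur)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 100)
  expect_equal(map_association(W, -W, sur)$r, -1)
  expect_error(map_association(rep(1, 40), W, sur), "zero-variance")
})

test_that("BH step-up matches hand-applied decisions", {
  out <- fdr_correct(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$p_adj, p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"))
  all_small <- fdr_correct(rep(0.001, 10), q = 0.05)
  expect_true(all(all_small$significant))
  single <- fdr_correct(0.04)
  expect_equal(single$p_adj, 0.04)
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("gene screen selects planted positives and never anti-correlated maps", {
  set.seed(12)
  geo <- region_geometry(50)
  D <- region_distances(geo)
  W <- abs(geo$z) + runif(50, 0, 0.2)
  W <- W / sum(W)
  sur <- variogram_surrogates(W, D, n_surrogates = 500, seed = 5)
  genes <- rbind(planted = W + rnorm(50, sd = 0.01 * sd(W)),
                 flipped = -W,
                 matrix(rnorm(50 * 20), 20, 50,
                        dimnames = list(sprintf("null%02d", 1:20), NULL)))
  res <- gene_map_screen(genes, W, sur, q = 0.1)
  expect_true(res$selected[res$gene == "planted"])
  expect_false(res$selected[res$gene == "flipped"])
  # missing-region genes are dropped with a message
  genes_na <- genes
  genes_na[3, 5] <- NA
  expect_message(gene_map_screen(genes_na, W, sur), "dropped 1")
})
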