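# synthetic cohort generator: bookkeeping, determinism, planted structure

test_that("cohort bookkeeping follows the configuration", {
  cfg <- sim_config(n_subjects = 6, n_regions = 12, n_timepoints = 30,
                    kinship_pairs = 2, seed = 7)
  co <- simulate_cohort(cfg)
  expect_s3_class(co, "bfp_cohort")
  expect_length(co$runs, 6 * 3 * 2)
  for (r in co$runs) {
    expect_equal(dim(r$matrix), c(12, 30))
    expect_true(all(is.finite(r$matrix)))
  }
  # one run per (subject, session, run) triple
  expect_false(anyDuplicated(co$index[, c("subject_id", "session", "run")]) > 0)
  # signatures live exactly on their masks
  for (p in co$profiles) {
    expect_true(all(p$signature[!p$signature_mask] == 0))
    expect_true(any(p$signature[p$signature_mask] != 0))
  }
})

test_that("the same seed reproduces the identical cohort", {
  cfg <- small_sim(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$runs, b$runs)
  expect_identical(a$scores, b$scores)
  expect_identical(a$kinship, b$kinship)
  c2 <- simulate_cohort(small_sim(seed = 43))
  expect_false(identical(a$runs[[1]]$matrix, c2$runs[[1]]$matrix))
})

test_that("config validation rejects out-of-range fields by name", {
  expect_error(sim_config(drift_rate = 1.2), "drift_rate")
  expect_error(sim_config(noise_ar1 = 2), "noise_ar1")
  expect_error(sim_config(signature_region_fraction = -0.1),
               "signature_region_fraction")
  expect_error(sim_config(n_subjects = 10, kinship_pairs = 6),
               "kinship_pairs")
  expect_error(sim_config(n_regions = 1), "n_regions")
  expect_error(sim_config(signature_strength = NaN), "signature_strength")
})

test_that("region geometry is deterministic with valid distances", {
  g1 <- region_geometry(60)
  g2 <- region_geometry(60)
  expect_identical(g1, g2)
  D2 <- region_distances(region_geometry(2))
  expect_equal(D2[1, 2], D2[2, 1])
  expect_gt(D2[1, 2], 0)
  expect_equal(unname(diag(D2)), rep(0, 2))
  # triangle inequality over all triples at R = 20
  D <- region_distances(region_geometry(20))
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)
})

test_that("kinship pairs are disjoint with first-degree coefficients", {
  co <- simulate_cohort(sim_config(n_subjects = 30, kinship_pairs = 5,
                                   seed = 3))
  kin <- make_kinship_pairs(co)
  expect_equal(nrow(kin), 5)
  ids <- c(kin$id_1, kin$id_2)
  expect_length(unique(ids), 10)
  expect_true(all(kin$pi_hat >= 0.5 & kin$pi_hat <= 1))
  co0 <- simulate_cohort(small_sim(kinship_pairs = 0))
  expect_equal(nrow(make_kinship_pairs(co0)), 0)
  # unrelated profiles carry pi_hat 0 and no partner
  unrel <- setdiff(unique(co$index$subject_id), ids)
  for (s in unrel) {
    expect_true(is.na(co$profiles[[s]]$kin_partner))
    expect_equal(co$profiles[[s]]$pi_hat, 0)
  }
})

test_that("related pairs share more signature than unrelated pairs", {
  set.seed(1)
  sims <- replicate(20, {
    co <- simulate_cohort(sim_config(n_subjects = 20, n_regions = 30,
                                     n_timepoints = 10, kinship_pairs = 5,
                                     kinship_share = 0.6,
                                     seed = sample.int(1e6, 1)))
    kin <- make_kinship_pairs(co)
    sig <- vapply(co$profiles, `[[`, numeric(30), "signature")
    cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    rel <- mean(mapply(function(a, b) cs(sig[, a], sig[, b]),
                       kin$id_1, kin$id_2))
    subj <- colnames(sig)
    pairs <- t(combn(subj, 2))
    key <- paste(pairs[, 1], pairs[, 2])
    relkey <- paste(kin$id_1, kin$id_2)
    unrel_pairs <- pairs[!key %in% relkey, , drop = FALSE]
    unrel <- mean(apply(unrel_pairs, 1, function(p) cs(sig[, p[1]],
                                                       sig[, p[2]])))
    rel - unrel
  })
  expect_gt(mean(sims), 0)
})

test_that("signature strength raises same-subject FC similarity monotonically", {
  fc_sim <- function(strength, seed) {
    co <- simulate_cohort(sim_config(n_subjects = 6, n_regions = 20,
                                     n_timepoints = 150, kinship_pairs = 0,
                                     signature_strength = strength,
                                     seed = seed))
    subj <- unique(co$index$subject_id)
    mean(vapply(subj, function(s) {
      f1 <- connectome_features(get_run(co, s, "baseline", 1))
      f2 <- connectome_features(get_run(co, s, "baseline", 2))
      cor(f1, f2)
    }, numeric(1)))
  }
  grid <- c(0, 1.5, 3)
  sims <- vapply(grid, function(st)
    mean(vapply(1:10, function(s) fc_sim(st, s), numeric(1))), numeric(1))
  expect_true(all(diff(sims) > 0))
})

test_that("zero signature strength removes the same-subject FC advantage", {
  diffs <- vapply(1:20, function(seed) {
    co <- simulate_cohort(sim_config(n_subjects = 6, n_regions = 15,
                                     n_timepoints = 100, kinship_pairs = 0,
                                     signature_strength = 0, seed = seed))
    subj <- unique(co$index$subject_id)
    feats1 <- vapply(subj, function(s)
      connectome_features(get_run(co, s, "baseline", 1)),
      numeric(15 * 14 / 2))
    feats2 <- vapply(subj, function(s)
      connectome_features(get_run(co, s, "baseline", 2)),
      numeric(15 * 14 / 2))
    C <- cor(feats1, feats2)
    mean(diag(C)) - mean(C[row(C) != col(C)])
  }, numeric(1))
  # same-subject minus different-subject similarity within Monte-Carlo error
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("session drift lowers cross-interval same-subject FC similarity", {
  diffs <- vapply(1:20, function(seed) {
    co <- simulate_cohort(sim_config(n_subjects = 5, n_regions = 20,
                                     n_timepoints = 150, kinship_pairs = 0,
                                     signature_strength = 1.5,
                                     drift_rate = 0.9, seed = seed))
    subj <- unique(co$index$subject_id)
    same_sess <- mean(vapply(subj, function(s)
      cor(connectome_features(get_run(co, s, "baseline", 1)),
          connectome_features(get_run(co, s, "baseline", 2))), numeric(1)))
    gap4 <- mean(vapply(subj, function(s)
      cor(connectome_features(get_run(co, s, "baseline", 1)),
          connectome_features(get_run(co, s, "year4", 1))), numeric(1)))
    same_sess - gap4
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  # and the full ordering holds on a desk-scale cohort, averaged over seeds
  ord <- rowMeans(vapply(1:5, function(seed) {
    co <- simulate_cohort(sim_config(n_subjects = 8, n_regions = 20,
                                     n_timepoints = 150, kinship_pairs = 0,
                                     seed = seed))
    subj <- unique(co$index$subject_id)
    sim_at <- function(sess) mean(vapply(subj, function(s)
      cor(connectome_features(get_run(co, s, "baseline", 1)),
          connectome_features(get_run(co, s, sess,
                                      if (sess == "baseline") 2 else 1))),
      numeric(1)))
    c(within = sim_at("baseline"), y2 = sim_at("year2"),
      y4 = sim_at("year4"))
  }, numeric(3)))
  expect_gte(ord["within"], ord["y2"])
  expect_gte(ord["y2"], ord["y4"])
})

test_that("noise-only regions carry the configured AR(1) autocorrelation", {
  co <- simulate_cohort(sim_config(n_subjects = 3, n_regions = 20,
                                   n_timepoints = 375, shared_strength = 0,
                                   transient_strength = 0,
                                   signature_strength = 0,
                                   noise_ar1 = 0.3, kinship_pairs = 0,
                                   seed = 5))
  acs <- unlist(lapply(co$runs[1:6], function(r)
    apply(r$matrix, 1, function(x)
      cor(x[-1], x[-length(x)]))))
  expect_lt(abs(mean(acs) - 0.3), 0.1)
  co2 <- simulate_cohort(sim_config(n_subjects = 3, n_regions = 20,
                                    n_timepoints = 375, shared_strength = 0,
                                    transient_strength = 0,
                                    signature_strength = 0,
                                    noise_ar1 = -0.4, kinship_pairs = 0,
                                    seed = 6))
  acs2 <- unlist(lapply(co2$runs[1:6], function(r)
    apply(r$matrix, 1, function(x) cor(x[-1], x[-length(x)]))))
  expect_lt(abs(mean(acs2) + 0.4), 0.1)
})

test_that("atlas has seven contiguous networks and matching geometry", {
  at <- cohort_atlas(60)
  expect_equal(nrow(at), 60)
  expect_length(unique(at$network_label), 7)
  expect_identical(at[, c("x", "y", "z")], region_geometry(60)[, c("x", "y", "z")])
})
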