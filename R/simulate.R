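#' Configuration for the synthetic longitudinal cohort simulator
#'
#' Defines the generative conditions for a multi-subject, multi-session
#' parcellated BOLD cohort with planted, recoverable individual signatures.
#' The generative model for each run is
#' \deqn{X = s_g A S + s_f v_{i,sess} g^\top + s_t B Z + E,}
#' a low-rank group component (mixing matrix `A` shared by the whole cohort,
#' fresh sinusoid-plus-noise temporal sources `S` per run), a rank-1 subject
#' signature (spatial loading `v` times a private temporal source `g`), a
#' rank-`k` run-specific transient ("state") component, and AR(1) regional
#' noise `E` with lag-1 autocorrelation `noise_ar1`.
#'
#' Session drift attenuates the *correlation* of the signature loading:
#' at `y` years from baseline the loading is
#' `rho * v + sqrt(1 - rho^2) * u_sess` with `rho = drift_rate^y`, so the
#' signature keeps its energy but decorrelates geometrically over time.
#' Members of a kinship pair share a fraction `kinship_share` of signature
#' variance (`v = sqrt(share) * common + sqrt(1 - share) * private`) and a
#' kinship coefficient `pi_hat` drawn in \[0.5, 1\]. Cognitive scores are a
#' fixed random projection of the baseline signature scaled by
#' `cognitive_weight` plus unit Gaussian noise.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of atlas regions R (>= 2).
#' @param n_timepoints time points T per run (>= 2).
#' @param session_years named numeric vector of session time offsets in
#'   years since baseline; names are the session labels.
#' @param runs_per_session scan runs acquired per session.
#' @param signature_strength amplitude of the subject-specific component.
#' @param signature_region_fraction fraction of regions carrying a
#'   signature, in \[0, 1\].
#' @param drift_rate per-year attenuation of signature correlation, \[0, 1\].
#' @param noise_ar1 lag-1 autocorrelation of regional noise, in (-1, 1).
#' @param shared_strength amplitude of the group (shared-source) component.
#' @param transient_strength amplitude of the run-specific state component.
#' @param n_shared_sources rank of the group component.
#' @param n_transient_sources rank of the run-specific state component.
#' @param kinship_pairs number of related (first-degree) subject pairs.
#' @param kinship_share fraction of signature variance shared within a
#'   related pair, in \[0, 1\].
#' @param cognitive_weight effect size linking the signature to the
#'   simulated cognitive scores.
#' @param seed random seed; identical config + seed gives a byte-identical
#'   cohort.
#' @return a list of class `bfp_sim_config`.
#' @export
sim_config <- function(n_subjects = 30L,
                       n_regions = 60L,
                       n_timepoints = 375L,
                       session_years = c(baseline = 0, year2 = 2, year4 = 4),
                       runs_per_session = 2L,
                       signature_strength = 1.5,
                       signature_region_fraction = 0.4,
                       drift_rate = 0.9,
                       noise_ar1 = 0.3,
                       shared_strength = 1,
                       transient_strength = 2,
                       n_shared_sources = 5L,
                       n_transient_sources = 3L,
                       kinship_pairs = 5L,
                       kinship_share = 0.6,
                       cognitive_weight = 1,
                       seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lo = 2, integerish = TRUE)
  check_scalar(n_regions, "n_regions", lo = 2, integerish = TRUE)
  check_scalar(n_timepoints, "n_timepoints", lo = 2, integerish = TRUE)
  if (is.null(names(session_years)) || any(!nzchar(names(session_years))))
    stop_named("session_years", "must be a named vector of year offsets")
  if (any(!is.finite(session_years)) || any(session_years < 0))
    stop_named("session_years", "offsets must be finite and >= 0")
  check_scalar(runs_per_session, "runs_per_session", lo = 1, integerish = TRUE)
  check_scalar(signature_strength, "signature_strength", lo = 0)
  check_scalar(signature_region_fraction, "signature_region_fraction", 0, 1)
  check_scalar(drift_rate, "drift_rate", 0, 1)
  check_scalar(noise_ar1, "noise_ar1", -1, 1)
  check_scalar(shared_strength, "shared_strength", lo = 0)
  check_scalar(transient_strength, "transient_strength", lo = 0)
  check_scalar(n_shared_sources, "n_shared_sources", lo = 1, integerish = TRUE)
  check_scalar(n_transient_sources, "n_transient_sources", lo = 1,
               integerish = TRUE)
  check_scalar(kinship_pairs, "kinship_pairs", lo = 0, integerish = TRUE)
  if (2 * kinship_pairs > n_subjects)
    stop_named("kinship_pairs", "2 * kinship_pairs exceeds n_subjects")
  check_scalar(kinship_share, "kinship_share", 0, 1)
  check_scalar(cognitive_weight, "cognitive_weight")
  check_scalar(seed, "seed", integerish = TRUE)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_regions = as.integer(n_regions),
              n_timepoints = as.integer(n_timepoints),
              session_years = session_years,
              runs_per_session = as.integer(runs_per_session),
              signature_strength = signature_strength,
              signature_region_fraction = signature_region_fraction,
              drift_rate = drift_rate,
              noise_ar1 = noise_ar1,
              shared_strength = shared_strength,
              transient_strength = transient_strength,
              n_shared_sources = as.integer(n_shared_sources),
              n_transient_sources = as.integer(n_transient_sources),
              kinship_pairs = as.integer(kinship_pairs),
              kinship_share = as.integer(0) + kinship_share,
              cognitive_weight = cognitive_weight,
              seed = as.integer(seed))
  class(cfg) <- "bfp_sim_config"
  cfg
}

# stationary AR(1) series with unit marginal variance
ar1_series <- function(n, phi) {
  innov <- rnorm(n)
  if (abs(phi) < 1e-12) return(innov)
  x <- numeric(n)
  x[1] <- innov[1]
  sc <- sqrt(1 - phi^2)
  for (t in 2:n) x[t] <- phi * x[t - 1] + sc * innov[t]
  x
}

# bursty private source: sparse activation events smoothed with an AR(1)
# kernel, scaled to unit variance (event-like co-activation dynamics)
event_series <- function(n, phi, rate = 0.08) {
  ev <- rnorm(n) * (runif(n) < rate)
  x <- as.numeric(stats::filter(ev, phi, method = "recursive"))
  s <- sd(x)
  if (s == 0) return(rnorm(n))   # degenerate draw: fall back to noise
  x / s
}

# sinusoid + noise group sources, unit variance rows (k x T)
shared_sources <- function(k, T) {
  S <- matrix(0, k, T)
  tt <- seq_len(T) / T
  for (j in seq_len(k)) {
    f <- runif(1, 1, 20)
    ph <- runif(1, 0, 2 * pi)
    s <- sqrt(2) * sin(2 * pi * f * tt + ph) + 0.35 * rnorm(T)
    S[j, ] <- s / sd(s)
  }
  S
}

masked_normal <- function(R, mask) {
  v <- numeric(R)
  v[mask] <- rnorm(sum(mask))
  v
}

#' Deterministic region geometry on a unit sphere
#'
#' Places R region centroids on a Fibonacci lattice over the sphere, giving
#' a deterministic, roughly uniform 3-D embedding whose pairwise distances
#' support variogram-based spatial surrogates.
#'
#' @param n_regions number of regions (>= 2).
#' @param radius sphere radius (arbitrary units).
#' @return data.frame with columns `region_id`, `x`, `y`, `z`.
#' @export
region_geometry <- function(n_regions, radius = 1) {
  check_scalar(n_regions, "n_regions", lo = 2, integerish = TRUE)
  i <- seq_len(n_regions) - 0.5
  golden <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / golden
  z <- 1 - 2 * i / n_regions
  r <- sqrt(pmax(0, 1 - z^2))
  data.frame(region_id = sprintf("r%03d", seq_len(n_regions)),
             x = radius * r * cos(theta),
             y = radius * r * sin(theta),
             z = radius * z)
}

#' Pairwise Euclidean distances between region centroids
#'
#' @param geometry data.frame from [region_geometry()] or any table with
#'   `x`, `y`, `z` columns.
#' @return symmetric distance matrix with zero diagonal.
#' @export
region_distances <- function(geometry) {
  as.matrix(dist(geometry[, c("x", "y", "z")]))
}

seven_networks <- c("Visual", "Somatomotor", "DorsalAttention",
                    "VentralAttention", "Limbic", "Frontoparietal",
                    "Default")

#' Synthetic atlas table
#'
#' Region identifiers, seven-network labels (assigned in contiguous blocks,
#' mimicking the spatial coherence of resting-state networks) and sphere
#' centroids for a synthetic parcellation.
#'
#' @inheritParams region_geometry
#' @return data.frame with columns `region_id`, `region_name`,
#'   `network_label`, `x`, `y`, `z`.
#' @export
cohort_atlas <- function(n_regions) {
  geo <- region_geometry(n_regions)
  blocks <- sort(rep_len(seq_along(seven_networks), n_regions))
  data.frame(region_id = geo$region_id,
             region_name = sprintf("region_%03d", seq_len(n_regions)),
             network_label = seven_networks[blocks],
             x = geo$x, y = geo$y, z = geo$z,
             stringsAsFactors = FALSE)
}

#' Simulate a longitudinal multi-subject BOLD cohort
#'
#' Generates one R x T run matrix per (subject, session, run) triple under
#' the generative model described in [sim_config()], together with the
#' ground-truth signature loadings, kinship pairs and cognitive scores
#' needed to validate downstream fingerprinting.
#'
#' All draws flow from `config$seed` in a fixed order, so the same
#' configuration always reproduces the identical cohort.
#'
#' @param config a [sim_config()] object.
#' @param generate_runs set `FALSE` to skip the BOLD run matrices and keep
#'   only profiles, scores and kinship (fast path for association-scale
#'   replicates). Profiles and scores are identical either way.
#' @return object of class `bfp_cohort`: a list with elements `config`,
#'   `atlas`, `profiles` (per-subject signature truth), `runs` (list of
#'   run records with fields `subject_id`, `session`, `years`, `run`,
#'   `matrix`), `index` (data.frame locating runs), `scores` (subjects x
#'   score table) and `kinship` (related-pair table).
#' @export
simulate_cohort <- function(config = sim_config(), generate_runs = TRUE) {
  if (!inherits(config, "bfp_sim_config"))
    config <- do.call(sim_config, config)
  set.seed(config$seed)
  R <- config$n_regions; T <- config$n_timepoints
  n <- config$n_subjects
  sess <- config$session_years
  subjects <- sprintf("sub%03d", seq_len(n))

  atlas <- cohort_atlas(R)

  A <- matrix(rnorm(R * config$n_shared_sources,
                    sd = 1 / sqrt(config$n_shared_sources)),
              R, config$n_shared_sources)

  # kinship pairing: first 2*kinship_pairs subjects, consecutive pairs
  kin_partner <- rep(NA_character_, n)
  pi_hat <- numeric(n)
  kp <- config$kinship_pairs
  if (kp > 0) {
    for (j in seq_len(kp)) {
      i1 <- 2 * j - 1; i2 <- 2 * j
      kin_partner[i1] <- subjects[i2]
      kin_partner[i2] <- subjects[i1]
      ph <- runif(1, 0.5, 1)
      pi_hat[i1] <- ph; pi_hat[i2] <- ph
    }
  }

  # cohort-level signature mask: the set of regions carrying individual
  # variability, drawn once with preference for the higher-order association
  # networks (where inter-individual FC variability concentrates in vivo)
  n_mask <- max(1L, round(config$signature_region_fraction * R))
  higher <- atlas$network_label %in% c("Default", "Frontoparietal",
                                      "VentralAttention")
  mask <- rep(FALSE, R)
  mask[sample.int(R, n_mask, prob = ifelse(higher, 3, 1))] <- TRUE

  profiles <- vector("list", n)
  names(profiles) <- subjects
  for (i in seq_len(n)) {
    related_lower <- !is.na(kin_partner[i]) && i %% 2 == 0
    if (related_lower) {
      # partner already drew the pair's shared component
      prev <- profiles[[subjects[match(kin_partner[i], subjects)]]]
      common <- attr(prev, "kin_common")
      sh <- config$kinship_share
      v <- sqrt(sh) * common + sqrt(1 - sh) * masked_normal(R, mask)
    } else if (!is.na(kin_partner[i])) {
      common <- masked_normal(R, mask)
      sh <- config$kinship_share
      v <- sqrt(sh) * common + sqrt(1 - sh) * masked_normal(R, mask)
    } else {
      common <- NULL
      v <- masked_normal(R, mask)
    }
    prof <- list(subject_id = subjects[i],
                 signature = v,
                 signature_mask = mask,
                 kin_partner = kin_partner[i],
                 pi_hat = pi_hat[i])
    attr(prof, "kin_common") <- common
    profiles[[i]] <- prof
  }

  # session-specific loadings: correlation decays as drift_rate^years
  for (i in seq_len(n)) {
    mask <- profiles[[i]]$signature_mask
    v0 <- profiles[[i]]$signature
    loadings <- list()
    for (s in names(sess)) {
      rho <- config$drift_rate^sess[[s]]
      if (sess[[s]] == 0) {
        loadings[[s]] <- v0
      } else {
        u <- masked_normal(R, mask)
        loadings[[s]] <- rho * v0 + sqrt(1 - rho^2) * u
      }
    }
    profiles[[i]]$session_loadings <- loadings
  }

  # cognitive scores load on the leading principal modes of across-subject
  # variation in the expected functional connectome. The raw loading v is
  # not used because its sign is unobservable (v g' and (-v)(-g)' generate
  # identical runs), and a random high-dimensional projection of the FC
  # pattern would be unrecoverable from any low-dimensional fingerprint;
  # tying behaviour to the dominant connectome variation modes mirrors the
  # empirical structure of cognition-connectome associations.
  score_names <- c("fluid", "crystallized", "executive", "total")
  n_modes <- length(score_names)
  n_edges <- R * (R - 1) / 2
  base_cov <- config$shared_strength^2 * tcrossprod(A) +
    diag(config$transient_strength^2 + 1, R)
  fc_mat <- vapply(profiles, function(p) {
    S <- base_cov + config$signature_strength^2 * tcrossprod(p$signature)
    FC <- S / tcrossprod(sqrt(diag(S)))
    FC[upper.tri(FC)]
  }, numeric(n_edges))                                            # edges x n
  fc_c <- fc_mat - rowMeans(fc_mat)
  sv <- svd(fc_c, nu = 0, nv = min(16L, n - 1L))
  mode_coords <- sv$v                       # n x k, orthonormal columns
  rownames(mode_coords) <- subjects
  mix <- matrix(rnorm(n_modes * min(n_modes, ncol(mode_coords))),
                n_modes, min(n_modes, ncol(mode_coords)))
  raw <- mix %*% t(mode_coords[, seq_len(ncol(mix)), drop = FALSE])
  raw <- t(scale(t(raw)))   # unit-variance signal across subjects
  noise <- matrix(rnorm(length(score_names) * n), length(score_names), n)
  scores_mat <- t(config$cognitive_weight * raw + noise)
  colnames(scores_mat) <- score_names
  scores <- data.frame(subject_id = subjects, scores_mat,
                       stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(n))
    profiles[[i]]$cognitive_scores <- setNames(as.numeric(scores_mat[i, ]),
                                               score_names)

  runs <- list()
  idx <- list()
  ri <- 0L
  if (generate_runs) for (i in seq_len(n)) {
    for (s in names(sess)) {
      v <- profiles[[i]]$session_loadings[[s]]
      for (r in seq_len(config$runs_per_session)) {
        S <- shared_sources(config$n_shared_sources, T)
        g <- event_series(T, max(config$noise_ar1, 0.3))
        B <- matrix(rnorm(R * config$n_transient_sources,
                          sd = 1 / sqrt(config$n_transient_sources)),
                    R, config$n_transient_sources)
        # state components are temporally smooth (arousal/drift-like):
        # they reshape run-to-run covariance without adding token-level
        # energy spikes
        Z <- t(vapply(seq_len(config$n_transient_sources),
                      function(j) ar1_series(T, 0.95), numeric(T)))
        E <- t(vapply(seq_len(R), function(j) ar1_series(T, config$noise_ar1),
                      numeric(T)))
        X <- config$shared_strength * (A %*% S) +
          config$signature_strength * tcrossprod(v, g) +
          config$transient_strength * (B %*% Z) +
          E
        ri <- ri + 1L
        runs[[ri]] <- list(subject_id = subjects[i], session = s,
                           years = unname(sess[[s]]), run = r, matrix = X)
        idx[[ri]] <- data.frame(subject_id = subjects[i], session = s,
                                years = unname(sess[[s]]), run = r,
                                stringsAsFactors = FALSE)
      }
    }
  }
  index <- if (length(idx) > 0) {
    ix <- do.call(rbind, idx)
    ix$run_index <- seq_len(nrow(ix))
    ix
  } else {
    data.frame(subject_id = character(0), session = character(0),
               years = numeric(0), run = integer(0),
               run_index = integer(0))
  }

  kinship <- if (kp > 0) {
    data.frame(id_1 = subjects[2 * seq_len(kp) - 1],
               id_2 = subjects[2 * seq_len(kp)],
               pi_hat = pi_hat[2 * seq_len(kp)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(id_1 = character(0), id_2 = character(0),
               pi_hat = numeric(0), stringsAsFactors = FALSE)
  }

  structure(list(config = config, atlas = atlas, profiles = profiles,
                 runs = runs, index = index, scores = scores,
                 kinship = kinship,
                 truth = list(signature_mask = mask,
                              shared_mixing = A,
                              fc_modes = mode_coords)),
            class = "bfp_cohort")
}

#' @export
print.bfp_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic BOLD cohort: %d subjects, %d regions, %d time points\n",
              cfg$n_subjects, cfg$n_regions, cfg$n_timepoints))
  cat(sprintf("  sessions: %s; %d run(s) per session; %d runs total\n",
              paste(sprintf("%s (+%gy)", names(cfg$session_years),
                            cfg$session_years), collapse = ", "),
              cfg$runs_per_session, length(x$runs)))
  cat(sprintf("  signature strength %.2f on %.0f%% of regions, drift %.2f/yr, %d kin pairs\n",
              cfg$signature_strength, 100 * cfg$signature_region_fraction,
              cfg$drift_rate, cfg$kinship_pairs))
  invisible(x)
}

#' Extract one run matrix from a cohort
#'
#' @param cohort a `bfp_cohort`.
#' @param subject subject identifier.
#' @param session session label.
#' @param run run number within session.
#' @return the R x T matrix.
#' @export
get_run <- function(cohort, subject, session, run = 1L) {
  i <- which(cohort$index$subject_id == subject &
               cohort$index$session == session &
               cohort$index$run == run)
  if (length(i) != 1L)
    stop(sprintf("no run for (%s, %s, run %d)", subject, session, run))
  cohort$runs[[i]]$matrix
}

#' Collect all run matrices for one (session, run) slot
#'
#' @inheritParams get_run
#' @param subjects optional subset of subject ids.
#' @return named list of R x T matrices, one per subject.
#' @export
session_runs <- function(cohort, session, run = 1L, subjects = NULL) {
  subjects <- subjects %||% unique(cohort$index$subject_id)
  out <- lapply(subjects, function(s) get_run(cohort, s, session, run))
  names(out) <- subjects
  out
}

#' Leading connectome-variation mode coordinates of a cohort
#'
#' Ground-truth utility: coordinates of each subject on the leading
#' principal modes of across-subject variation in the expected functional
#' connectome (the ideal, noise-free fingerprint representation). The
#' simulated cognitive scores load on the first four of these modes, so
#' these coordinates bound what any fingerprinting method can recover.
#'
#' @param cohort a simulated `bfp_cohort`.
#' @param k number of modes (up to 16).
#' @return subjects x k matrix with orthonormal columns.
#' @export
connectome_modes <- function(cohort, k = 16L) {
  if (is.null(cohort$truth))
    stop("connectome modes are only available for simulated cohorts")
  m <- cohort$truth$fc_modes
  m[, seq_len(min(k, ncol(m))), drop = FALSE]
}

#' Related-pair table of a cohort
#'
#' Returns the cohort's disjoint related pairs with their kinship
#' coefficients (`pi_hat` >= 0.5, first-degree relatives by construction).
#'
#' @param cohort a `bfp_cohort`.
#' @return data.frame with columns `id_1`, `id_2`, `pi_hat`.
#' @export
make_kinship_pairs <- function(cohort) {
  stopifnot(inherits(cohort, "bfp_cohort"))
  cohort$kinship
}
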