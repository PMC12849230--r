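#' Cosine distance between two vectors
#'
#' `d(u, v) = 1 - cos(u, v)`, in \[0, 2\]: the distance used both in the
#' triplet loss and at identification time. Scale-invariant and symmetric;
#' undefined (an error) for zero vectors.
#'
#' @param u,v numeric vectors of equal length.
#' @return distance in \[0, 2\].
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("cosine distance undefined for non-finite vectors")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine distance undefined for zero vectors")
  1 - sum(u * v) / (nu * nv)
}

#' Pairwise cosine distances between the rows of two matrices
#'
#' @param a,b matrices with vectors in rows (same number of columns).
#' @return nrow(a) x nrow(b) distance matrix.
#' @export
cosine_distance_matrix <- function(a, b = a) {
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0))
    stop("cosine distance undefined for zero vectors")
  1 - tcrossprod(a / na, b / nb)
}

#' Triplet margin loss
#'
#' `max(d(a,p) - d(a,n) + margin, 0)`: positive when the negative is not at
#' least `margin` farther from the anchor than the positive, zero
#' otherwise.
#'
#' @param d_ap anchor-positive distance(s), in \[0, 2\].
#' @param d_an anchor-negative distance(s), in \[0, 2\].
#' @param margin positive margin in distance units.
#' @return loss value(s), >= 0.
#' @export
triplet_loss <- function(d_ap, d_an, margin) {
  if (any(d_ap < 0) || any(d_an < 0)) stop("distances must be non-negative")
  if (any(margin <= 0)) stop("margin must be positive")
  pmax(d_ap - d_an + margin, 0)
}

#' Mine triplets from a batch of run pairs
#'
#' Every batch subject contributes a run pair; for each subject its two
#' runs form the anchor and positive, and every run of every other subject
#' in the batch serves as a negative. With `both_orderings = TRUE` the run
#' pair is additionally used in the reversed (positive, anchor) role, as in
#' training.
#'
#' @param subjects character vector, one entry per batch run (each subject
#'   must appear exactly twice).
#' @param both_orderings also emit the reversed anchor/positive roles.
#' @return integer matrix with columns `a`, `p`, `n` indexing into the
#'   batch.
#' @export
mine_batch <- function(subjects, both_orderings = FALSE) {
  tab <- table(subjects)
  if (any(tab != 2L))
    stop("each batch subject must contribute exactly one run pair")
  if (length(tab) < 2L) stop("a batch needs at least 2 subjects")
  uniq <- names(tab)
  out <- list()
  for (s in uniq) {
    own <- which(subjects == s)
    neg <- which(subjects != s)
    out[[length(out) + 1L]] <-
      cbind(a = own[1], p = own[2], n = neg)
    if (both_orderings)
      out[[length(out) + 1L]] <-
        cbind(a = own[2], p = own[1], n = neg)
  }
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  m
}

#' Hold-out split of subjects
#'
#' @param subjects character vector of subject ids.
#' @param fractions named numeric vector summing to 1 (e.g. the standard
#'   `c(train = .8, validation = .1, test = .1)`).
#' @param seed shuffle seed.
#' @return list of class `bfp_split` mapping split name -> subject ids.
#' @export
holdout_split <- function(subjects,
                          fractions = c(train = 0.8, validation = 0.1,
                                        test = 0.1),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_named("fractions", "must sum to 1")
  set.seed(seed)
  subjects <- sample(subjects)
  n <- length(subjects)
  sizes <- floor(fractions * n)
  while (sum(sizes) < n) {
    i <- which.max(fractions * n - sizes)
    sizes[i] <- sizes[i] + 1L
  }
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- Map(function(s, e) if (e >= s) subjects[s:e] else character(0),
             starts, ends)
  names(out) <- names(fractions)
  structure(out, class = "bfp_split", scheme = "holdout")
}

#' Group-conserved k-fold split
#'
#' Partitions groups (e.g. acquisition sites or families) into `k` folds,
#' never splitting a group across folds, while greedily balancing subject
#' counts.
#'
#' @param subjects character vector of subject ids.
#' @param groups group label per subject.
#' @param k number of folds (cannot exceed the number of distinct groups).
#' @param seed shuffle seed used to break ordering ties.
#' @return list of class `bfp_split` with `k` folds of subject ids.
#' @export
grouped_kfold_split <- function(subjects, groups, k, seed = 1L) {
  if (length(groups) != length(subjects))
    stop("every subject needs a group label")
  gsizes <- table(groups)
  if (k > length(gsizes))
    stop(sprintf("k = %d exceeds the number of groups (%d)", k,
                 length(gsizes)))
  set.seed(seed)
  ord <- names(gsizes)[order(-as.integer(gsizes),
                             sample.int(length(gsizes)))]
  fold_of <- setNames(integer(length(ord)), ord)
  load <- integer(k)
  for (g in ord) {
    f <- which.min(load)
    fold_of[g] <- f
    load[f] <- load[f] + gsizes[[g]]
  }
  out <- lapply(seq_len(k), function(f)
    subjects[fold_of[as.character(groups)] == f])
  names(out) <- sprintf("fold%d", seq_len(k))
  structure(out, class = "bfp_split", scheme = "grouped_kfold",
            fold_of = fold_of)
}

#' Training configuration for the metric encoder
#'
#' @param margin triplet margin (distance units, > 0).
#' @param batch_size subjects per batch (>= 2).
#' @param learning_rate Adam step size.
#' @param epochs passes over the training subjects.
#' @param margin_grid candidate margins for validation-based selection.
#' @param weight_decay L2 penalty (default 0).
#' @param checkpoint_every checkpoint cadence in epochs.
#' @param seed seed controlling batching, dropout and initialisation.
#' @return list of class `bfp_training_config`.
#' @export
training_config <- function(margin = 0.7,
                            batch_size = 8L,
                            learning_rate = 1e-3,
                            epochs = 20L,
                            margin_grid = c(0.3, 0.5, 0.7, 0.8, 0.9, 1.0),
                            weight_decay = 0,
                            checkpoint_every = 1L,
                            seed = 1L) {
  check_scalar(margin, "margin", lo = 1e-12)
  check_scalar(batch_size, "batch_size", lo = 2, integerish = TRUE)
  check_scalar(learning_rate, "learning_rate", lo = 0)
  check_scalar(epochs, "epochs", lo = 1, integerish = TRUE)
  check_scalar(weight_decay, "weight_decay", lo = 0)
  check_scalar(checkpoint_every, "checkpoint_every", lo = 1,
               integerish = TRUE)
  structure(list(margin = margin, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 margin_grid = margin_grid, weight_decay = weight_decay,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "bfp_training_config")
}

# recursive elementwise ops over nested parameter lists
walk2 <- function(a, b, f) {
  if (is.list(a)) return(Map(function(x, y) walk2(x, y, f), a, b))
  f(a, b)
}
walk1 <- function(a, f) {
  if (is.list(a)) return(lapply(a, walk1, f = f))
  f(a)
}

adam_init <- function(params) {
  list(m = walk1(params, function(x) x * 0),
       v = walk1(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0)
    grads <- walk2(grads, params, function(g, p) g + weight_decay * p)
  state$m <- walk2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- walk2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- walk2(state$m, state$v,
               function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- walk2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}

collect_pair_runs <- function(cohort, subjects, session_pair, run_pair) {
  enc_cfg <- NULL
  runs <- vector("list", 2L * length(subjects))
  labels <- character(2L * length(subjects))
  for (i in seq_along(subjects)) {
    runs[[2 * i - 1]] <- get_run(cohort, subjects[i], session_pair[1],
                                 run_pair[1])
    runs[[2 * i]] <- get_run(cohort, subjects[i], session_pair[2],
                             run_pair[2])
    labels[c(2 * i - 1, 2 * i)] <- subjects[i]
  }
  list(runs = runs, subjects = labels)
}

#' Fit the metric fingerprint encoder
#'
#' Trains the windowed transformer so that fingerprints of the same subject
#' cluster and fingerprints of different subjects separate, by minimising
#' the triplet cosine-margin loss over batches of subject run pairs with
#' Adam. Within each batch every other subject's runs serve as negatives,
#' and both orderings of a subject's run pair are used as anchor/positive.
#'
#' @param cohort a `bfp_cohort` (or any object supporting [get_run()]).
#' @param subjects subjects to train on (default: all in the cohort).
#' @param session_pair length-2 session labels supplying the run pair
#'   (default: the two baseline runs, i.e. a within-session pairing).
#' @param run_pair length-2 run numbers matching `session_pair`.
#' @param encoder an [encoder_config()]; default desk-scale configuration
#'   derived from the cohort.
#' @param training a [training_config()].
#' @param verbose print per-epoch mean loss.
#' @return object of class `fingerprint_model` with elements `params`
#'   (trained), `init_params`, `encoder`, `training`, `log` (per-epoch
#'   mean loss and active-triplet fraction), `checkpoints` (per-epoch
#'   parameter snapshots), and the training provenance.
#' @export
fit_fingerprint_model <- function(cohort,
                                  subjects = NULL,
                                  session_pair = c("baseline", "baseline"),
                                  run_pair = c(1L, 2L),
                                  encoder = NULL,
                                  training = training_config(),
                                  verbose = FALSE) {
  subjects <- subjects %||% unique(cohort$index$subject_id)
  if (length(subjects) < training$batch_size)
    stop("training needs at least `batch_size` subjects with a run pair")
  encoder <- encoder %||% encoder_config(n_regions = cohort$config$n_regions)

  data <- collect_pair_runs(cohort, subjects, session_pair, run_pair)
  mats <- lapply(data$runs, prep_run_matrix, config = encoder)
  cfg_cpp <- cfg_for_cpp(encoder)

  set.seed(training$seed)
  params <- init_encoder(encoder, seed = training$seed)
  init_params <- params
  opt <- adam_init(params)

  n_sub <- length(subjects)
  bs <- training$batch_size
  log_rows <- list()
  checkpoints <- list()

  for (epoch in seq_len(training$epochs)) {
    ord <- sample.int(n_sub)
    batch_starts <- seq(1L, n_sub, by = bs)
    losses <- c(); active <- c()
    for (b0 in batch_starts) {
      sel <- ord[b0:min(b0 + bs - 1L, n_sub)]
      if (length(sel) < 2L) next
      run_idx <- as.vector(rbind(2L * sel - 1L, 2L * sel))
      batch_subj <- data$subjects[run_idx]
      trip <- mine_batch(batch_subj, both_orderings = TRUE)
      res <- cpp_triplet_grad(mats[run_idx], trip, params, cfg_cpp,
                              training$margin, TRUE)
      if (!is.finite(res$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      upd <- adam_step(params, res$grads, opt, training$learning_rate,
                       training$weight_decay)
      params <- upd$params
      opt <- upd$state
      losses <- c(losses, res$loss)
      active <- c(active, res$n_active / nrow(trip))
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    mean_loss = mean(losses),
                                    active_fraction = mean(active))
    if (epoch %% training$checkpoint_every == 0L)
      checkpoints[[length(checkpoints) + 1L]] <-
        list(epoch = epoch, params = params)
    if (verbose)
      message(sprintf("epoch %3d  mean loss %.5f  active %.2f",
                      epoch, mean(losses), mean(active)))
  }

  structure(list(params = params,
                 init_params = init_params,
                 encoder = encoder,
                 training = training,
                 log = do.call(rbind, log_rows),
                 checkpoints = checkpoints,
                 subjects = subjects,
                 session_pair = session_pair,
                 run_pair = run_pair,
                 call = match.call()),
            class = "fingerprint_model")
}

#' @export
print.fingerprint_model <- function(x, ...) {
  e <- x$encoder
  cat("Metric fingerprint encoder (windowed transformer)\n")
  cat(sprintf("  %d regions -> %d-dim fingerprints; %d block(s), %d head(s), window %d/stride %d/fringe %d\n",
              e$n_regions, e$embed_dim, e$n_blocks, e$n_heads,
              e$window_length, e$window_stride, e$fringe_length))
  cat(sprintf("  trained on %d subjects (%s run pair), margin %.2f, %d epochs; final mean loss %.4f\n",
              length(x$subjects),
              paste(unique(x$session_pair), collapse = "/"),
              x$training$margin, x$training$epochs,
              x$log$mean_loss[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.fingerprint_model <- function(object, ...) {
  out <- list(encoder = object$encoder,
              training = object$training,
              n_subjects = length(object$subjects),
              n_parameters = sum(unlist(walk1(object$params,
                                              function(x) length(x)))),
              log = object$log)
  class(out) <- "summary.fingerprint_model"
  out
}

#' @export
print.summary.fingerprint_model <- function(x, ...) {
  cat(sprintf("fingerprint_model: %d parameters, %d training subjects\n",
              x$n_parameters, x$n_subjects))
  cat(sprintf("  loss %.4f -> %.4f over %d epochs (active triplets %.2f -> %.2f)\n",
              x$log$mean_loss[1], x$log$mean_loss[nrow(x$log)],
              nrow(x$log), x$log$active_fraction[1],
              x$log$active_fraction[nrow(x$log)]))
  invisible(x)
}

#' @export
plot.fingerprint_model <- function(x, ...) {
  plot(x$log$epoch, x$log$mean_loss, type = "b", xlab = "epoch",
       ylab = "mean triplet loss", main = "training progress", ...)
  invisible(x)
}

#' @export
coef.fingerprint_model <- function(object, ...) {
  object$params$Wp
}

#' Compute fingerprints for one (session, run) slot of a cohort
#'
#' @param model a `fingerprint_model` (or a bare list with `params` and
#'   `encoder`).
#' @param cohort a `bfp_cohort`.
#' @param session session label.
#' @param run run number.
#' @param subjects optional subject subset.
#' @param params parameter set to use (defaults to the trained parameters;
#'   pass `model$init_params` for the untrained encoder).
#' @return matrix (subjects x embed_dim) with subject ids as rownames and
#'   attributes `session` and `run`.
#' @export
fingerprints <- function(model, cohort, session, run = 1L, subjects = NULL,
                         params = model$params) {
  subjects <- subjects %||% unique(cohort$index$subject_id)
  out <- t(vapply(subjects, function(s) {
    encode_run(get_run(cohort, s, session, run), params,
               model$encoder)$fingerprint
  }, numeric(model$encoder$embed_dim)))
  rownames(out) <- subjects
  attr(out, "session") <- session
  attr(out, "run") <- run
  out
}

#' @rdname fingerprints
#' @param object,... predict-method interface: `object` is the model,
#'   remaining arguments are passed to [fingerprints()].
#' @export
predict.fingerprint_model <- function(object, ...) {
  fingerprints(object, ...)
}

#' Select the triplet margin on a validation set
#'
#' Trains one model per candidate margin and keeps the margin whose
#' validation success rate (within-session identification on the
#' validation subjects) is highest; ties break toward the smaller margin.
#'
#' @param cohort a `bfp_cohort`.
#' @param train_subjects,validation_subjects disjoint subject sets.
#' @param margin_grid candidate margins.
#' @param encoder,training encoder and training configurations (the
#'   margin field of `training` is overridden per candidate).
#' @param session_pair,run_pair run pairing, as in
#'   [fit_fingerprint_model()].
#' @return list with `margin` (selected), `validation_sr` per candidate,
#'   and the fitted model at the selected margin.
#' @export
select_margin <- function(cohort, train_subjects, validation_subjects,
                          margin_grid = c(0.3, 0.5, 0.7, 0.8, 0.9, 1.0),
                          encoder = NULL, training = training_config(),
                          session_pair = c("baseline", "baseline"),
                          run_pair = c(1L, 2L)) {
  if (length(intersect(train_subjects, validation_subjects)) > 0L)
    stop("train and validation subjects overlap")
  srs <- numeric(length(margin_grid))
  fits <- vector("list", length(margin_grid))
  for (i in seq_along(margin_grid)) {
    tc <- training
    tc$margin <- margin_grid[i]
    fit <- fit_fingerprint_model(cohort, subjects = train_subjects,
                                 session_pair = session_pair,
                                 run_pair = run_pair,
                                 encoder = encoder, training = tc)
    db <- fingerprints(fit, cohort, session_pair[1], run_pair[1],
                       subjects = validation_subjects)
    tg <- fingerprints(fit, cohort, session_pair[2], run_pair[2],
                       subjects = validation_subjects)
    srs[i] <- success_rate(identify_subjects(tg, db))
    fits[[i]] <- fit
  }
  best <- which.max(srs)
  list(margin = margin_grid[best],
       validation_sr = setNames(srs, margin_grid),
       model = fits[[best]])
}
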