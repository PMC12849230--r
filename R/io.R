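fmt_num <- function(x) format(x, digits = 17, scientific = TRUE,
                              trim = TRUE)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write a cohort to a TSV directory container
#'
#' One TSV per run (regions as rows, a header row of 0-based time
#' indices), plus `manifest.json` (config and run listing), `atlas.tsv`,
#' `covariates.tsv` and `kinship.tsv`. Floats are written with 17
#' significant digits for round-trip fidelity.
#'
#' @param cohort a `bfp_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "runs"), showWarnings = FALSE)
  files <- character(length(cohort$runs))
  for (i in seq_along(cohort$runs)) {
    r <- cohort$runs[[i]]
    fn <- sprintf("%s_%s_run%d.tsv", r$subject_id, r$session, r$run)
    m <- r$matrix
    df <- data.frame(region_id = cohort$atlas$region_id,
                     apply(m, 2L, fmt_num), check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("region_id", sprintf("t%04d", seq_len(ncol(m)) - 1L))
    write_tsv(df, file.path(dir, "runs", fn))
    files[i] <- fn
  }
  manifest <- list(
    format = "brainfp-cohort-tsv/1",
    config = cohort$config[setdiff(names(cohort$config), NULL)],
    runs = data.frame(cohort$index[, c("subject_id", "session", "years",
                                       "run")],
                      file = files, stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(cohort$atlas, file.path(dir, "atlas.tsv"))
  write_tsv(cohort$scores, file.path(dir, "covariates.tsv"))
  write_tsv(cohort$kinship, file.path(dir, "kinship.tsv"))
  invisible(dir)
}

#' Read a cohort from a TSV directory container
#'
#' Validates the manifest, checks every run file exists, has the atlas's
#' region order, a consistent region count and finite values. Runs may
#' have differing lengths T; differing region counts are an error.
#'
#' @param dir directory written by [write_cohort()].
#' @return object of class `bfp_cohort` (without simulation ground truth).
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  atlas <- read_tsv(file.path(dir, "atlas.tsv"))
  problems <- character(0)
  runs <- vector("list", nrow(manifest$runs))
  R <- NA_integer_
  for (i in seq_len(nrow(manifest$runs))) {
    row <- manifest$runs[i, ]
    path <- file.path(dir, "runs", row$file)
    if (!file.exists(path)) {
      problems <- c(problems, sprintf("missing run file: %s", row$file))
      next
    }
    df <- read_tsv(path, colClasses = "character")
    m <- apply(as.matrix(df[, -1, drop = FALSE]), c(1, 2), as.numeric)
    if (is.na(R)) R <- nrow(m)
    if (nrow(m) != R)
      problems <- c(problems,
                    sprintf("%s: %d regions, expected %d", row$file,
                            nrow(m), R))
    if (!identical(df$region_id, atlas$region_id))
      problems <- c(problems,
                    sprintf("%s: region order differs from atlas", row$file))
    if (any(!is.finite(m)))
      problems <- c(problems, sprintf("%s: non-finite values", row$file))
    dimnames(m) <- NULL
    runs[[i]] <- list(subject_id = row$subject_id, session = row$session,
                      years = row$years, run = row$run, matrix = m)
  }
  if (length(problems) > 0L)
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  index <- manifest$runs[, c("subject_id", "session", "years", "run")]
  index$run_index <- seq_len(nrow(index))
  scores_path <- file.path(dir, "covariates.tsv")
  kin_path <- file.path(dir, "kinship.tsv")
  structure(list(config = manifest$config, atlas = atlas,
                 profiles = NULL, runs = runs, index = index,
                 scores = if (file.exists(scores_path))
                   read_tsv(scores_path) else NULL,
                 kinship = if (file.exists(kin_path))
                   read_tsv(kin_path) else NULL),
            class = "bfp_cohort")
}

#' Write fingerprints to TSV
#'
#' Columns: `subject_id`, `session`, `run`, `v1` .. `vD`.
#'
#' @param fp fingerprint matrix from [fingerprints()].
#' @param path output file.
#' @export
write_fingerprints <- function(fp, path) {
  df <- data.frame(subject_id = rownames(fp),
                   session = attr(fp, "session") %||% NA,
                   run = attr(fp, "run") %||% NA,
                   apply(unclass(fp), 2L, fmt_num),
                   stringsAsFactors = FALSE)
  colnames(df) <- c("subject_id", "session", "run",
                    sprintf("v%d", seq_len(ncol(fp))))
  write_tsv(df, path)
  invisible(path)
}

#' Read fingerprints from TSV
#'
#' @param path file from [write_fingerprints()].
#' @return fingerprint matrix with subject rownames and session/run
#'   attributes.
#' @export
read_fingerprints <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, grep("^v\\d+$", colnames(df)), drop = FALSE])
  rownames(m) <- df$subject_id
  colnames(m) <- NULL
  attr(m, "session") <- df$session[1]
  attr(m, "run") <- df$run[1]
  m
}

interval_pairs <- function() {
  list(within = list(a = c("baseline", 1L), b = c("baseline", 2L)),
       year2 = list(a = c("baseline", 1L), b = c("year2", 1L)),
       year4 = list(a = c("baseline", 1L), b = c("year4", 1L)))
}

#' Run the full fingerprinting pipeline on a synthetic cohort
#'
#' Simulate -> train -> fingerprint -> identify (three intervals, both
#' directions, with permutation test and connectome baseline) ->
#' interpret (token/region importance, network contrasts, annotation-map
#' association with spatial surrogates) -> associate (score regression and
#' kinship distance test, the latter on a model retrained without related
#' subjects, mirroring the recommended ordering). Writes a JSON report and
#' returns it invisibly.
#'
#' @param sim a [sim_config()].
#' @param encoder an [encoder_config()] (default derived from `sim`).
#' @param training a [training_config()].
#' @param out_dir output directory for `report.json` and artifacts
#'   (`NULL` skips writing).
#' @param n_permutations permutations for the identification null.
#' @param n_surrogates surrogate maps for the annotation-map test.
#' @param seed global seed; every stage derives its stream from it.
#' @param verbose print stage progress.
#' @return report list, invisibly.
#' @export
run_pipeline <- function(sim = sim_config(),
                         encoder = NULL,
                         training = training_config(),
                         out_dir = NULL,
                         n_permutations = 1000L,
                         n_surrogates = 200L,
                         seed = 1L,
                         verbose = FALSE) {
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(stage, msg = "start", level = "info") {
    line <- jsonlite::toJSON(list(stage = stage, level = level,
                                  message = msg,
                                  elapsed = round(as.numeric(
                                    difftime(Sys.time(), t0,
                                             units = "secs")), 3)),
                             auto_unbox = TRUE)
    log_lines <<- c(log_lines, as.character(line))
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  sim$seed <- as.integer(seed)
  training$seed <- as.integer(seed)

  say("simulate")
  cohort <- simulate_cohort(sim)
  encoder <- encoder %||% encoder_config(n_regions = sim$n_regions,
                                         seed = seed)

  say("train")
  model <- fit_fingerprint_model(cohort, encoder = encoder,
                                 training = training)

  say("identify")
  ident <- list()
  for (iv in names(interval_pairs())) {
    pr <- interval_pairs()[[iv]]
    fa <- fingerprints(model, cohort, pr$a[1], as.integer(pr$a[2]))
    fb <- fingerprints(model, cohort, pr$b[1], as.integer(pr$b[2]))
    both <- bidirectional_evaluate(fa, fb,
                                   labels = c(paste(pr$a, collapse = "/"),
                                              paste(pr$b, collapse = "/")),
                                   n_permutations = n_permutations,
                                   seed = seed)
    base <- connectome_baseline(
      session_runs(cohort, pr$a[1], as.integer(pr$a[2])),
      session_runs(cohort, pr$b[1], as.integer(pr$b[2])))
    ident[[iv]] <- list(
      forward = both$forward[c("SR", "CR", "SC", "p_value", "max_null")],
      reverse = both$reverse[c("SR", "CR", "SC")],
      connectome = base[c("SR", "CR", "SC")])
  }

  say("interpret")
  subj <- unique(cohort$index$subject_id)
  runs <- session_runs(cohort, "baseline", 1L)
  imps <- lapply(runs, function(x) token_importance(model, x))
  W <- region_contribution(runs, imps, seed = seed)
  contrasts <- network_contrast(W, cohort$atlas$network_label)
  D <- region_distances(cohort$atlas)
  mask <- cohort$truth$signature_mask
  # annotation-map demo: smooth geometry gradient, tested against W
  grad_map <- cohort$atlas$z
  sur <- variogram_surrogates(grad_map, D, n_surrogates = n_surrogates,
                              seed = seed)
  map_assoc <- map_association(W, grad_map, sur)
  interp <- list(W = as.numeric(W),
                 signature_auc = roc_auc(W, mask),
                 network_contrasts = contrasts,
                 gradient_map_association = map_assoc)

  say("associate")
  fp_base <- fingerprints(model, cohort, "baseline", 1L)
  assoc <- list()
  if (length(subj) > encoder$embed_dim + 1L) {
    reg <- fingerprint_regression(fp_base,
                                  cohort$scores$fluid[
                                    match(rownames(fp_base),
                                          cohort$scores$subject_id)])
    assoc$regression <- reg[c("F", "df1", "df2", "p")]
  }
  kin <- make_kinship_pairs(cohort)
  if (nrow(kin) >= 2L) {
    related_ids <- unique(c(kin$id_1, kin$id_2))
    unrelated <- setdiff(subj, related_ids)
    kin_model <- if (length(unrelated) >= training$batch_size) {
      fit_fingerprint_model(cohort, subjects = unrelated,
                            encoder = encoder, training = training)
    } else model
    fp_kin <- fingerprints(kin_model, cohort, "baseline", 1L)
    pairs <- fingerprint_pair_distances(fp_kin, kin)
    assoc$kinship <- kinship_distance_test(pairs)
  }

  report <- list(seed = seed,
                 config = list(simulation = unclass(sim),
                               encoder = unclass(encoder),
                               training = unclass(training)),
                 identification = ident,
                 interpretation = interp,
                 association = assoc)
  say("pipeline", "complete")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(log_lines, file.path(out_dir, "log.jsonl"))
  }
  invisible(report)
}
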