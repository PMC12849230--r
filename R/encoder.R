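#' Windowed transformer encoder configuration
#'
#' Defines the architecture that maps one R x T BOLD matrix to a
#' fingerprint vector: BOLD tokens (one linear projection per time point),
#' temporally overlapping windows each carrying a dedicated CLS token,
#' `n_blocks` of windowed multi-head attention with token fusion across
#' overlapping windows, and averaging of the final CLS states.
#'
#' Within a window, the CLS token and the window's BOLD tokens attend to
#' the window's tokens plus `fringe_length` tokens on each side. A learned
#' positional encoding indexed by within-window offset is added to token
#' states at window-gather time.
#'
#' @param n_regions number of atlas regions R.
#' @param embed_dim token/fingerprint dimension (divisible by `n_heads`).
#' @param window_length time points per window.
#' @param window_stride time points between window starts; must not exceed
#'   `window_length`. Equality (zero overlap) is permitted with a warning.
#' @param fringe_length extra time points attended on each side of a window.
#' @param n_blocks number of transformer blocks (0 gives the degenerate
#'   encoder whose fingerprint is the shared CLS initialisation).
#' @param n_heads attention heads.
#' @param mlp_hidden hidden width of the token-wise MLP.
#' @param dropout dropout rate in \[0, 1), applied during training only.
#' @param zscore z-score each region's time series inside the encoder.
#' @param seed seed for parameter initialisation.
#' @return list of class `bfp_encoder_config`.
#' @export
encoder_config <- function(n_regions,
                           embed_dim = 32L,
                           window_length = 20L,
                           window_stride = 10L,
                           fringe_length = 10L,
                           n_blocks = 2L,
                           n_heads = 4L,
                           mlp_hidden = 2L * embed_dim,
                           dropout = 0.1,
                           zscore = TRUE,
                           seed = 1L) {
  check_scalar(n_regions, "n_regions", lo = 1, integerish = TRUE)
  check_scalar(embed_dim, "embed_dim", lo = 1, integerish = TRUE)
  check_scalar(window_length, "window_length", lo = 1, integerish = TRUE)
  check_scalar(window_stride, "window_stride", lo = 1, integerish = TRUE)
  check_scalar(fringe_length, "fringe_length", lo = 0, integerish = TRUE)
  check_scalar(n_blocks, "n_blocks", lo = 0, integerish = TRUE)
  check_scalar(n_heads, "n_heads", lo = 1, integerish = TRUE)
  check_scalar(mlp_hidden, "mlp_hidden", lo = 1, integerish = TRUE)
  check_scalar(dropout, "dropout", lo = 0, hi = 1 - 1e-9)
  if (window_stride > window_length)
    stop_named("window_stride", "must not exceed window_length (windows must tile)")
  if (window_stride == window_length)
    warning("window_stride equals window_length: consecutive windows do not overlap")
  if (embed_dim %% n_heads != 0)
    stop_named("embed_dim", "must be divisible by n_heads")
  structure(list(n_regions = as.integer(n_regions),
                 embed_dim = as.integer(embed_dim),
                 window_length = as.integer(window_length),
                 window_stride = as.integer(window_stride),
                 fringe_length = as.integer(fringe_length),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 dropout = dropout,
                 zscore = isTRUE(zscore),
                 seed = as.integer(seed)),
            class = "bfp_encoder_config")
}

#' Window slices for a time series length
#'
#' Applies the slicing rule: windows of `window_length` points start every
#' `window_stride` points from 0 while they fit; if uncovered points remain
#' a final right-aligned tail window is added. Indices are 0-based,
#' half-open `[start, stop)`.
#'
#' @param n_timepoints series length T (>= `window_length`).
#' @param window_length,window_stride window geometry.
#' @return data.frame with columns `start` and `stop`.
#' @export
window_slices <- function(n_timepoints, window_length, window_stride) {
  if (n_timepoints < window_length)
    stop(sprintf("time series (T=%d) shorter than window_length=%d; use a shorter window",
                 n_timepoints, window_length))
  starts <- seq(0L, n_timepoints - window_length, by = window_stride)
  if (max(starts) + window_length < n_timepoints)
    starts <- c(starts, n_timepoints - window_length)
  data.frame(start = starts, stop = starts + window_length)
}

#' Initialise encoder parameters
#'
#' Draws all learnable parameters (token projection, per-offset positional
#' encoding, shared CLS initialisation, per-block attention and MLP
#' weights) from seeded Gaussians.
#'
#' @param config an [encoder_config()].
#' @param seed overrides `config$seed` if given.
#' @return nested parameter list as consumed by the C++ encoder.
#' @export
init_encoder <- function(config, seed = config$seed) {
  set.seed(seed)
  d <- config$embed_dim
  h <- config$mlp_hidden
  Lr <- config$window_length + 2L * config$fringe_length
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    list(Wq = matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d), bq = numeric(d),
         Wk = matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d), bk = numeric(d),
         Wv = matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d), bv = numeric(d),
         Wo = matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d), bo = numeric(d),
         W1 = matrix(rnorm(d * h, sd = 1 / sqrt(d)), d, h), b1 = numeric(h),
         W2 = matrix(rnorm(h * d, sd = 1 / sqrt(h)), h, d), b2 = numeric(d))
  })
  list(Wp = matrix(rnorm(config$n_regions * d, sd = 1 / sqrt(config$n_regions)),
                   config$n_regions, d),
       bp = numeric(d),
       pos = matrix(rnorm(Lr * d, sd = 0.02), Lr, d),
       cls0 = rnorm(d),
       blocks = blocks)
}

cfg_for_cpp <- function(config) {
  config[c("n_regions", "embed_dim", "window_length", "window_stride",
           "fringe_length", "n_blocks", "n_heads", "mlp_hidden", "dropout")]
}

prep_run_matrix <- function(x, config) {
  if (!is.matrix(x)) stop("run must be an R x T numeric matrix")
  if (nrow(x) != config$n_regions)
    stop(sprintf("run has %d regions but the encoder expects %d",
                 nrow(x), config$n_regions))
  if (any(!is.finite(x))) stop("run matrix contains non-finite values")
  if (isTRUE(config$zscore)) zscore_rows(x) else x
}

#' BOLD tokenisation
#'
#' Projects each time point's R-vector to `embed_dim` with the learned
#' linear projection (after optional per-region z-scoring), yielding one
#' token per time point. Positional encodings are added later, at
#' window-gather time, because a token's within-window offset differs
#' across the overlapping windows it belongs to.
#'
#' @param x R x T run matrix.
#' @param config an [encoder_config()].
#' @param params parameters from [init_encoder()] or a fitted model.
#' @return T x embed_dim token matrix.
#' @export
tokenize <- function(x, config, params) {
  x <- prep_run_matrix(x, config)
  sweep(crossprod(x, params$Wp), 2L, params$bp, `+`)
}

#' Encode one run into a fingerprint
#'
#' Runs the full windowed-transformer forward pass and returns the
#' fingerprint (mean of final CLS states) together with, optionally, the
#' CLS attention record used for token attribution. Dropout is inactive:
#' encoding is deterministic given parameters.
#'
#' @param x R x T run matrix.
#' @param params encoder parameters.
#' @param config an [encoder_config()].
#' @param record_attention also return per-block, per-window, per-head
#'   CLS-to-token attention rows.
#' @return list with `fingerprint` (length embed_dim), `n_windows`,
#'   `window_starts` (1-based), `cls_states`, and `attention` if requested.
#' @export
encode_run <- function(x, params, config, record_attention = FALSE) {
  x <- prep_run_matrix(x, config)
  cpp_encode(x, params, cfg_for_cpp(config), record_attention)
}
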