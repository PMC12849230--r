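# encoder: windowing rule, tokenisation, determinism, attention record

test_that("window slicing follows the stride rule with a right-aligned tail", {
  ws <- window_slices(375, 20, 10)
  expect_equal(nrow(ws), 37)                       # 36 strided + 1 tail
  expect_equal(ws$start[1:36], seq(0, 350, by = 10))
  expect_equal(ws$stop[36], 370)
  expect_equal(c(ws$start[37], ws$stop[37]), c(355, 375))
  # full coverage of [0, T)
  covered <- rep(FALSE, 375)
  for (i in seq_len(nrow(ws))) covered[(ws$start[i] + 1):ws$stop[i]] <- TRUE
  expect_true(all(covered))
  # consecutive strided windows overlap by window_length - stride
  expect_equal(ws$stop[1] - ws$start[2], 10)
  # T == window_length gives a single window
  ws1 <- window_slices(20, 20, 10)
  expect_equal(nrow(ws1), 1)
  expect_equal(c(ws1$start, ws1$stop), c(0, 20))
  expect_error(window_slices(10, 20, 10), "shorter")
})

test_that("encoder config enforces its invariants", {
  expect_error(encoder_config(5, window_length = 10, window_stride = 11),
               "must not exceed")
  expect_warning(encoder_config(5, window_length = 10, window_stride = 10),
                 "do not overlap")
  expect_error(encoder_config(5, embed_dim = 30, n_heads = 4), "divisible")
  expect_error(encoder_config(5, dropout = 1), "dropout")
})

test_that("tokenisation is a linear projection of z-scored series", {
  cfg <- tiny_encoder()
  params <- init_encoder(cfg)
  x <- random_run(5, 30, seed = 2)
  tok <- tokenize(x, cfg, params)
  expect_equal(dim(tok), c(30, 8))
  # zero matrix with zero bias gives all-zero tokens
  p0 <- params; p0$bp[] <- 0
  cfg_nz <- cfg; cfg_nz$zscore <- FALSE
  expect_equal(tokenize(matrix(0, 5, 30), cfg_nz, p0), matrix(0, 30, 8))
  # region-wise constant shifts vanish under internal z-scoring
  shift <- x + matrix(c(5, -2, 0.3, 100, -7), 5, 30)
  expect_equal(tokenize(shift, cfg, params), tok, tolerance = 1e-10)
})

test_that("encoding is deterministic, shape-stable and length-flexible", {
  cfg <- tiny_encoder(dropout = 0.1)   # dropout must not affect inference
  params <- init_encoder(cfg)
  x <- random_run(5, 40, seed = 4)
  e1 <- encode_run(x, params, cfg)
  e2 <- encode_run(x, params, cfg)
  expect_identical(e1$fingerprint, e2$fingerprint)
  expect_length(e1$fingerprint, 8)
  expect_equal(e1$n_windows, nrow(window_slices(40, 6, 3)))
  # scanner-protocol-length series (T = 1200) encode unchanged
  long <- random_run(5, 1200, seed = 5)
  e3 <- encode_run(long, params, cfg)
  expect_length(e3$fingerprint, 8)
  expect_equal(e3$n_windows, nrow(window_slices(1200, 6, 3)))
  expect_true(all(is.finite(e3$fingerprint)))
  # shape and validation errors
  expect_error(encode_run(random_run(4, 40), params, cfg), "regions")
  bad <- x; bad[2, 3] <- NA
  expect_error(encode_run(bad, params, cfg), "non-finite")
})

test_that("with no blocks the fingerprint is the shared CLS initialisation", {
  cfg <- encoder_config(n_regions = 4, embed_dim = 6, window_length = 5,
                        window_stride = 3, fringe_length = 1, n_blocks = 0,
                        n_heads = 2, dropout = 0, seed = 8)
  params <- init_encoder(cfg)
  e <- encode_run(random_run(4, 20, seed = 2), params, cfg)
  expect_equal(e$fingerprint, params$cls0)
})

test_that("attention rows are normalised and cover the fringe receptive field", {
  cfg <- tiny_encoder()
  params <- init_encoder(cfg)
  x <- random_run(5, 31, seed = 6)
  e <- encode_run(x, params, cfg, record_attention = TRUE)
  expect_length(e$attention, cfg$n_blocks)
  ws <- window_slices(31, cfg$window_length, cfg$window_stride)
  for (blk in e$attention) {
    expect_length(blk, nrow(ws))
    for (f in seq_along(blk)) {
      win <- blk[[f]]
      expect_equal(win$core_start, ws$start[f] + 1)
      expect_equal(win$rf_start, max(1, ws$start[f] + 1 - cfg$fringe_length))
      expect_equal(win$rf_end, min(31, ws$stop[f] + cfg$fringe_length))
      for (a_h in win$cls_attention) {
        expect_length(a_h, win$rf_end - win$rf_start + 1)
        expect_true(all(a_h >= 0))
        expect_equal(sum(a_h), 1, tolerance = 1e-5)
      }
    }
  }
})

test_that("parameter count grows with width and depth but not with T", {
  n_par <- function(cfg) {
    p <- init_encoder(cfg)
    sum(vapply(rapply(p, length, how = "unlist"), identity, numeric(1)))
  }
  base <- tiny_encoder()
  wider <- tiny_encoder(); wider$embed_dim <- 16L; wider$mlp_hidden <- 20L
  deeper <- tiny_encoder(); deeper$n_blocks <- 4L
  expect_gt(n_par(wider), n_par(base))
  expect_gt(n_par(deeper), n_par(base))
  # encoding different lengths re-uses the same parameter set
  params <- init_encoder(base)
  for (T in c(12, 50, 200))
    expect_length(encode_run(random_run(5, T, seed = T), params,
                             base)$fingerprint, 8)
})
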