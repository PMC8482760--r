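# Path-level behaviour: loss closed form, gating, injection wiring,
# inference determinism. Uses stub checkpoints so no training is needed.

stub_ckpt <- function(path_id, const_out = 0, seed = 1) {
  cfg <- tiny_cfg(path_id)
  params <- bnet:::bnet_params_init(cfg, seed = seed)
  structure(list(params = params, cfg = cfg, aux_mean = 0, aux_sd = 1,
                 target_mean = if (path_id == 1) 0 else c(0, 0),
                 target_sd = if (path_id == 1) 1 else c(1, 1)),
            class = "bnet_checkpoint")
}

test_that("smooth l1: piecewise closed form, continuity, gradient bound", {
  expect_equal(smooth_l1(2, 2), 0)
  expect_equal(smooth_l1(3, 0), 2.5)
  expect_equal(smooth_l1(0.4, 0), 0.5 * 0.16)
  # continuity and differentiability at |x - y| = 1
  eps <- 1e-9
  expect_equal(smooth_l1(1 - eps, 0), smooth_l1(1 + eps, 0),
               tolerance = 1e-7)
  expect_equal(smooth_l1(1, 0), 0.5)
  # even, non-negative, zero iff equal
  set.seed(1)
  d <- rnorm(100)
  expect_equal(smooth_l1(d, 0), smooth_l1(-d, 0))
  expect_true(all(smooth_l1(d, 0) >= 0))
  expect_true(all(abs(bnet:::smooth_l1_grad(d * 5, 0)) <= 1))
})

test_that("count rounding: nearest, half away from zero, clamped", {
  expect_identical(round_count(c(0.4, 0.5, 1.49, 1.5, 2.5)),
                   c(0L, 1L, 1L, 2L, 3L))
  expect_identical(round_count(c(-0.2, -3)), c(0L, 0L))
})

test_that("zeroed path-1 head predicts 0 after clamping; inference deterministic", {
  ck <- stub_ckpt(1)
  ck$params$fc2$w[] <- 0
  ck$params$fc2$b[] <- -0.5
  set.seed(2)
  x <- matrix(rnorm(4 * 64), 4, 64)
  expect_equal(predict_count(ck, x), rep(0, 4))
  ck2 <- stub_ckpt(1, seed = 3)
  p1 <- predict_count(ck2, x)
  p2 <- predict_count(ck2, x)
  expect_identical(p1, p2)
})

test_that("count injection is live and feature inference deterministic", {
  ck <- stub_ckpt(2)
  set.seed(4)
  x <- matrix(rnorm(3 * 64), 3, 64)
  f1 <- predict_features(ck, x, c(1, 1, 1))
  f2 <- predict_features(ck, x, c(5, 5, 5))
  expect_false(isTRUE(all.equal(f1, f2)))
  expect_identical(predict_features(ck, x, c(2, 2, 2)),
                   predict_features(ck, x, c(2, 2, 2)))
})

test_that("gating: rounded zero count short-circuits to (0,0,0)", {
  ck1 <- stub_ckpt(1)
  ck2 <- stub_ckpt(2)
  set.seed(5)
  x <- matrix(rnorm(4 * 64), 4, 64)
  # force path 1 to zero: zero head
  ck1$params$fc2$w[] <- 0; ck1$params$fc2$b[] <- 0
  # poison path 2: if it were invoked on gated windows the result would
  # be nonzero with overwhelming probability
  out <- bnet_predict(ck1, ck2, x, window_s = 0.5)
  expect_equal(out$count, rep(0L, 4))
  expect_equal(out$mean_amplitude_nA, rep(0, 4))
  expect_equal(out$mean_duration_ms, rep(0, 4))
  expect_equal(out$frequency_Hz, rep(0, 4))
  # force path 1 positive: windows flow to path 2 with the raw count
  ck1$params$fc2$b[] <- 3.2
  out2 <- bnet_predict(ck1, ck2, x, window_s = 0.5)
  expect_equal(out2$count, rep(3L, 4))
  expect_equal(out2$frequency_Hz, rep(3 / 0.5, 4))
  expect_equal(out2$mean_amplitude_nA,
               unname(predict_features(ck2, x, out2$count_raw)[, 1]))
})

test_that("training smoke: loss decreases, contracts hold, reproducible", {
  # tiny dataset with strong signal so 5 epochs show a trend
  grid <- data.frame(c_np_nM = 1, d_np_nm = 14, duration_ms = 3)
  ds <- generate_dataset(grid, snr = Inf,
                         windows_per_split = c(train = 24, val = 8,
                                               test = 8),
                         seed = 31, trace_length_s = 2)
  cfg <- bnet_config(1, base_width = 8, head_hidden = 8)
  sch <- train_schedule(4, 1, n_epochs = 5)
  ck <- train_path(1, ds, schedule = sch, seed = 41, cfg = cfg)
  expect_s3_class(ck, "bnet_checkpoint")
  expect_identical(nrow(ck$history), 5L)
  expect_lt(ck$history$train_loss[5], ck$history$train_loss[1])
  # reproducibility: same seed, same best epoch, same parameters
  ck2 <- train_path(1, ds, schedule = sch, seed = 41, cfg = cfg)
  expect_identical(ck$best_epoch, ck2$best_epoch)
  expect_equal(ck$params$fc2$w, ck2$params$fc2$w, tolerance = 1e-12)
  # schedule regimes as stated
  s_high <- train_schedule(4, 1)
  expect_identical(s_high$batch_size, 32L)
  expect_equal(s_high$decay_multiplier, 0.1)
  expect_identical(s_high$decay_every_epochs, 10L)
  s_low <- train_schedule(0.25, 2)
  expect_identical(s_low$batch_size, 8L)
  expect_equal(s_low$decay_multiplier, 0.8)
  expect_identical(s_low$decay_every_epochs, 20L)
})

test_that("path 2 trains only on event windows and never mutates path 1", {
  grid <- data.frame(c_np_nM = 1, d_np_nm = 14, duration_ms = 3)
  ds <- generate_dataset(grid, snr = Inf,
                         windows_per_split = c(train = 16, val = 8,
                                               test = 8),
                         seed = 33, trace_length_s = 2)
  cfg2 <- bnet_config(2, base_width = 8, head_hidden = 8)
  sch <- train_schedule(4, 2, n_epochs = 2)
  ck2 <- train_path(2, ds, schedule = sch, seed = 42, cfg = cfg2)
  expect_s3_class(ck2, "bnet_checkpoint")
  # a dataset with empty-only training windows is a config error
  ds0 <- ds
  ds0$train$labels$count[] <- 0
  expect_error(train_path(2, ds0, schedule = sch, seed = 1, cfg = cfg2),
               "event-containing")
})
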