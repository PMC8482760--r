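test_that("event sampling: empty at zero concentration, contract fields", {
  cond <- sim_condition(0, 10, 1, trace_length_s = 2)
  set.seed(1)
  expect_identical(nrow(sample_events(cond, 0.3)), 0L)
  cond2 <- sim_condition(1, 10, 1, trace_length_s = 5)
  set.seed(2)
  ev <- sample_events(cond2, 0.29)
  expect_true(all(ev$t_start_s >= 0 & ev$t_start_s < 5))
  expect_true(all(ev$t_end_s <= 5))
  expect_false(is.unsorted(ev$t_start_s))
  expect_equal(ev$t_end_s - ev$t_start_s, ev$duration_ms / 1000)
  expect_true(all(ev$rise_fraction > 0.2 & ev$rise_fraction < 0.8))
  expect_error(sample_events(sim_condition(1, 10, 1), 0.3, k_cap = 1e5),
               "probability")
})

test_that("event counts are Binomial with mean k_cap * c * T", {
  # oracle: Binomial mean; 200 replicates of a 10 s trace at c = 1 nM
  cond <- sim_condition(1, 10, 0.5, trace_length_s = 10)
  set.seed(42)
  counts <- replicate(200, nrow(sample_events(cond, 0.3)))
  expected <- 20 * 1 * 10
  se <- sqrt(expected * (1 - 20 / 10000) / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # variance/mean ~ 1 - p
  expect_lt(abs(var(counts) / mean(counts) - (1 - 20 / 10000)), 0.15)
})

test_that("spike waveform: apex, symmetry, area", {
  w <- spike_waveform(1, 0.3, 0.5, 10000)
  expect_length(w, 10)
  expect_equal(max(w), 0.3)
  # rise_fraction = 0.5 with odd interior: symmetric about the apex
  w2 <- spike_waveform(1.1, 1, 0.5, 10000)
  expect_equal(w2, rev(w2))
  # triangle area oracle: 0.5 * A * duration within one sample's worth
  a <- sum(w) / 10000
  expect_lt(abs(a - 0.5 * 0.3 * 1e-3), 0.3 / 10000)
  expect_error(spike_waveform(0.05, 0.3, 0.5, 10000), "degenerate")
})

test_that("colored-noise synthesis matches the target PSD and RMS", {
  pp <- noise_psd_params()
  zero <- noise_psd_params(a_flicker = 0, a_electrode = 0, a_white = 0,
                           a_dielectric = 0)
  set.seed(3)
  expect_equal(synth_colored_noise(zero, 4096, 10000), rep(0, 4096))
  set.seed(4)
  y <- synth_colored_noise(pp, 2^18, 10000)
  expect_lt(abs(sqrt(mean(y^2)) / noise_rms(pp) - 1), 0.03)
  expect_lt(abs(mean(y)), 1e-3 * sqrt(mean(y^2)) * 50)
})

test_that("baseline: constant without perturbations, drift mean ~ 0", {
  set.seed(5)
  b <- synth_baseline(10000, 10000, 4.2,
                      jump_cfg = list(rate_per_s = 0),
                      drift_cfg = list(amp_frac = 0))
  expect_equal(b, rep(4.2, 10000))
  # drift-only baseline: time-mean of the drift within 1% of its scale
  set.seed(6)
  n <- 60 * 10000  # 60 s >> slowest period (20 s)
  d <- synth_baseline(n, 10000, 4.2, jump_cfg = list(rate_per_s = 0),
                      drift_cfg = list(amp_frac = 0.005)) - 4.2
  expect_lt(abs(mean(d)), 0.01 * 8 * 0.005 * 4.2)
  # jump count is Binomial with mean rate * T
  set.seed(7)
  njump <- replicate(50, {
    b <- synth_baseline(20000, 10000, 4.2,
                        jump_cfg = list(rate_per_s = 1),
                        drift_cfg = list(amp_frac = 0))
    sum(diff(b) != 0)
  })
  expect_lt(abs(mean(njump) - 2), 3 * sqrt(2 / 50))
})

test_that("generate_trace composes parts exactly and reproducibly", {
  tr <- fixture_trace()
  # same seed -> bit-identical
  tr2 <- generate_trace(tr$condition, seed = 7)
  expect_identical(tr$noisy, tr2$noisy)
  expect_identical(tr$events, tr2$events)
  # zero events -> clean equals baseline (noise-free, c = 0)
  tr0 <- generate_trace(sim_condition(0, 10, 1, snr = Inf,
                                      trace_length_s = 1), seed = 3)
  expect_identical(nrow(tr0$events), 0L)
  expect_identical(tr0$noisy, tr0$clean)
  # at each event apex, baseline - clean recovers the amplitude
  tr_iso <- generate_trace(sim_condition(0.2, 12, 2, snr = Inf,
                                         trace_length_s = 5),
                           seed = 11, jump_cfg = list(rate_per_s = 0),
                           drift_cfg = list(amp_frac = 0))
  ev <- tr_iso$events
  # use isolated events only (no overlap with neighbours)
  iso <- which(c(TRUE, diff(ev$t_start_s) > 2 * ev$duration_ms[1] / 1000) &
                 c(diff(ev$t_start_s) > 2 * ev$duration_ms[1] / 1000, TRUE))
  expect_gt(length(iso), 0)
  for (i in iso[seq_len(min(5, length(iso)))]) {
    seg <- round(ev$t_start_s[i] * 10000):round(ev$t_end_s[i] * 10000) + 1L
    depth <- max(tr_iso$i0_nA - tr_iso$clean[seg])
    expect_equal(depth, ev$amplitude_nA[i], tolerance = 1e-9)
  }
})

test_that("noisy - clean is the calibrated noise; realized SNR on target", {
  tr <- fixture_trace()
  resid <- tr$noisy - tr$clean
  expect_lt(abs(mean(resid)), 0.01 * tr$noise_rms_nA)
  expect_lt(abs(sqrt(mean(resid^2)) / tr$noise_rms_nA - 1), 0.03)
  snr_real <- tr$amplitude_nA / (6 * sqrt(mean(resid^2)))
  expect_lt(abs(snr_real / tr$condition$snr - 1), 0.05)
})

test_that("ground-truth labels agree with an independent clean-trace scan", {
  # independent oracle: scan the noise-free trace (flat baseline) for
  # dips below half the known amplitude and count the excursions
  tr <- generate_trace(sim_condition(0.3, 10, 1, snr = Inf,
                                     trace_length_s = 5),
                       seed = 13, jump_cfg = list(rate_per_s = 0),
                       drift_cfg = list(amp_frac = 0))
  dep <- tr$i0_nA - tr$clean
  below <- dep > tr$amplitude_nA / 2
  runs <- rle(below)
  n_exc <- sum(runs$values)
  # excursions equal events when no two events overlap at half depth
  gap <- diff(tr$events$t_start_s)
  if (all(gap > tr$events$duration_ms[1] / 1000))
    expect_equal(n_exc, nrow(tr$events))
})

test_that("generate_dataset honors the grid and exact window counts", {
  expect_identical(nrow(default_grid()), 1500L)
  grid <- expand.grid(c_np_nM = c(0.1, 1), d_np_nm = c(8, 14),
                      duration_ms = c(1, 3), KEEP.OUT.ATTRS = FALSE)
  ds <- generate_dataset(grid, snr = 4,
                         windows_per_split = c(train = 25, val = 12,
                                               test = 7),
                         seed = 5, trace_length_s = 2)
  expect_identical(nrow(ds$train$x), 25L)
  expect_identical(nrow(ds$val$x), 12L)
  expect_identical(nrow(ds$test$x), 7L)
  expect_identical(ncol(ds$train$x), 5000L)
  expect_true(all(ds$manifest$split %in% c("train", "val", "test")))
  # bundle round trip from the manifest
  dir <- withr::local_tempdir()
  ds2 <- generate_dataset(grid[1, , drop = FALSE], snr = 4,
                          windows_per_split = c(train = 4, val = 4,
                                                test = 4),
                          seed = 5, trace_length_s = 2, dir = dir)
  m <- ds2$manifest
  tr <- read_bundle(m$path[1])
  tr_re <- generate_trace(sim_condition(m$c_np_nM[1], m$d_np_nm[1],
                                        m$duration_ms[1], snr = 4,
                                        trace_length_s = 2),
                          seed = m$seed[1])
  expect_identical(tr$noisy, tr_re$noisy)
  expect_identical(tr$events, tr_re$events)
})
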