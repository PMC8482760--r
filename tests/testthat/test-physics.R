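test_that("effective conductivity follows the surface-conduction model", {
  p <- pore_spec(); e <- electrolyte()
  # oracle: hand evaluation of kappa_bulk + 4 mu |sigma| / d
  expect_equal(effective_conductivity(p, e),
               1.28 + 4 * 7.62e-8 * 0.02 / 20e-9, tolerance = 1e-12)
  expect_equal(effective_conductivity(p, e), 1.5848, tolerance = 1e-4)
  # surface term vanishes for an uncharged pore
  expect_equal(effective_conductivity(pore_spec(surface_charge_C_per_m2 = 0),
                                      e), 1.28)
  # 1/d limit: a 1 mm pore is bulk-dominated to < 0.1%
  wide <- pore_spec(diameter_nm = 1e6)
  expect_lt(abs(effective_conductivity(wide, e) / 1.28 - 1), 1e-3)
  expect_error(pore_spec(diameter_nm = -1), "diameter")
})

test_that("open-pore current: series-resistance formula, linear in bias", {
  p <- pore_spec(); e <- electrolyte()
  # oracle: hand evaluation of V / [(4L/(pi d^2) + 1/d)/kappa] in nA
  d <- 20e-9; L <- 20e-9; kap <- effective_conductivity(p, e)
  i_hand <- 0.3 / ((4 * L / (pi * d^2) + 1 / d) / kap) * 1e9
  expect_equal(open_pore_current(p, e, 0.3), i_hand, tolerance = 1e-12)
  expect_equal(open_pore_current(p, e, 0.3), 4.18, tolerance = 2e-3)
  expect_equal(open_pore_current(p, e, 0), 0)
  expect_equal(open_pore_current(p, e, 0.6),
               2 * open_pore_current(p, e, 0.3))
  # strictly increasing in pore diameter
  i_big <- open_pore_current(pore_spec(diameter_nm = 25), e, 0.3)
  expect_gt(i_big, open_pore_current(p, e, 0.3))
})

test_that("blockade amplitude: steric model, monotone, bias-invariant ratio", {
  p <- pore_spec(); e <- electrolyte()
  i0 <- open_pore_current(p, e, 0.3)
  # oracle: hand evaluation 1000/(400*36) * I0
  expect_equal(blockade_amplitude(p, 10, i0), i0 * 1000 / (400 * 36),
               tolerance = 1e-12)
  expect_equal(blockade_amplitude(p, 10, i0), 0.290, tolerance = 2e-3)
  amps <- blockade_amplitude(p, 3:17, i0)
  expect_true(all(diff(amps) > 0))
  expect_lt(blockade_amplitude(p, 1e-3, i0), 1e-9)
  expect_error(blockade_amplitude(p, 21, i0), "translocate")
  # dI/I0 independent of bias voltage
  i0b <- open_pore_current(p, e, 0.15)
  expect_equal(blockade_amplitude(p, 8, i0) / i0,
               blockade_amplitude(p, 8, i0b) / i0b)
})

test_that("noise PSD: four components, shape and errors", {
  flat <- noise_psd_params(a_flicker = 0, a_electrode = 0, a_white = 3e-8,
                           a_dielectric = 0)
  expect_equal(noise_psd(flat, c(1, 10, 1000)), rep(3e-8, 3))
  fl <- noise_psd_params(a_flicker = 1e-6, beta = 1, a_electrode = 0,
                         a_white = 0, a_dielectric = 0)
  expect_equal(noise_psd(fl, 200), noise_psd(fl, 100) / 2)
  pp <- noise_psd_params()
  # term-by-term hand sum at 100 Hz
  expect_equal(noise_psd(pp, 100),
               pp$a_flicker / 100 + pp$a_electrode / sqrt(100) +
                 pp$a_white + pp$a_dielectric * 100)
  expect_error(noise_psd(pp, 0), "frequency")
  # dominance ordering with defaults: flicker -> electrode -> white -> dielectric
  term <- function(f) c(pp$a_flicker / f^pp$beta, pp$a_electrode / f^pp$gamma,
                        pp$a_white, pp$a_dielectric * f)
  expect_equal(which.max(term(5)), 1L)
  expect_equal(which.max(term(100)), 2L)
  expect_equal(which.max(term(1000)), 3L)
  expect_equal(which.max(term(4900)), 4L)
})

test_that("noise RMS agrees with closed forms and is component-additive", {
  flat <- noise_psd_params(a_flicker = 0, a_electrode = 0, a_white = 4e-8,
                           a_dielectric = 0, f_min_Hz = 1e-6, f_max_Hz = 5000)
  expect_equal(noise_rms(flat), sqrt(4e-8 * (5000 - 1e-6)), tolerance = 1e-9)
  fl <- noise_psd_params(a_flicker = 2e-6, beta = 1, a_electrode = 0,
                         a_white = 0, a_dielectric = 0,
                         f_min_Hz = 1, f_max_Hz = 5000)
  expect_equal(noise_rms(fl), sqrt(2e-6 * log(5000)), tolerance = 1e-6)
  zero <- noise_psd_params(a_flicker = 0, a_electrode = 0, a_white = 0,
                           a_dielectric = 0)
  expect_equal(noise_rms(zero), 0)
  # variance additivity across components, 1e-9 relative
  full <- noise_psd_params()
  parts <- list(
    noise_psd_params(a_electrode = 0, a_white = 0, a_dielectric = 0),
    noise_psd_params(a_flicker = 0, a_white = 0, a_dielectric = 0),
    noise_psd_params(a_flicker = 0, a_electrode = 0, a_dielectric = 0),
    noise_psd_params(a_flicker = 0, a_electrode = 0, a_white = 0))
  expect_equal(noise_rms(full),
               sqrt(sum(vapply(parts, function(p) noise_rms(p)^2, 1))),
               tolerance = 1e-9)
})

test_that("SNR noise scaling enforces the amplitude/(p2p*rms) definition", {
  sp <- snr_spec(4, 6)
  # A = 1.2, snr = 4 -> required rms 0.05
  s <- snr_noise_scale(sp, 1.2, 0.02)
  expect_equal(s * 0.02, 0.05)
  # doubling snr halves required RMS
  expect_equal(snr_noise_scale(snr_spec(8, 6), 1.2, 0.02) * 0.02, 0.025)
  # base rms already correct -> scale 1
  expect_equal(snr_noise_scale(sp, 1.2, 0.05), 1)
  # closed-form identity: A / (p2p * scaled rms) = snr exactly
  expect_equal(1.2 / (6 * s * 0.02), 4)
  expect_equal(snr_noise_scale(snr_spec(Inf), 1, 0.02), 0)
  expect_error(snr_noise_scale(sp, 1.2, 0), "RMS")
})
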