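#' Simulation condition
#'
#' One cell of the generating grid: nanosphere concentration (sets event
#' frequency), nanosphere diameter (sets blockade amplitude), assigned
#' translocation duration, target SNR, bias voltage, trace length and
#' sampling rate.
#'
#' @param c_np_nM Nanosphere concentration in nM (>= 0).
#' @param d_np_nm Nanosphere diameter in nm.
#' @param duration_ms Dwell time assigned to every event, in ms.
#' @param snr Target SNR (`Inf` = noise-free).
#' @param bias_V Bias voltage in volts.
#' @param trace_length_s Trace length in seconds.
#' @param fs_Hz Sampling rate in Hz (default 10 kHz).
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(c_np_nM, d_np_nm, duration_ms, snr = 4,
                          bias_V = 0.3, trace_length_s = 5, fs_Hz = 10000) {
  stopifnot(c_np_nM >= 0, d_np_nm > 0, duration_ms > 0, snr > 0,
            trace_length_s > 0, fs_Hz > 0)
  n <- fs_Hz * trace_length_s
  if (abs(n - round(n)) > 1e-9)
    stop("fs_Hz * trace_length_s must be an integer number of samples")
  structure(list(c_np_nM = c_np_nM, d_np_nm = d_np_nm,
                 duration_ms = duration_ms, snr = snr, bias_V = bias_V,
                 trace_length_s = trace_length_s, fs_Hz = fs_Hz),
            class = "sim_condition")
}

empty_event_table <- function() {
  data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
             duration_ms = numeric(0), amplitude_nA = numeric(0),
             rise_fraction = numeric(0))
}

#' Sample translocation events for a condition
#'
#' Events appear by a per-time-step Bernoulli trial with probability
#' `p = k_cap * c_np * dt`, so the expected count over a trace of length
#' `T` is `k_cap * c_np * T`. Every event carries the condition's assigned
#' duration, the steric-blockade amplitude of the condition's sphere
#' diameter, and a rise fraction drawn from Uniform(0.2, 0.8). Starts are
#' restricted so events end inside the trace. Uses the current R RNG
#' state.
#'
#' @param cond A [sim_condition()].
#' @param amplitude_nA Blockade amplitude for this condition (nA).
#' @param k_cap Capture-rate constant in events/s/nM (default 20).
#' @return An event table `data.frame`, sorted by start time, with columns
#'   `t_start_s`, `t_end_s`, `duration_ms`, `amplitude_nA`, `rise_fraction`.
#' @export
sample_events <- function(cond, amplitude_nA, k_cap = 20) {
  stopifnot(inherits(cond, "sim_condition"))
  p <- k_cap * cond$c_np_nM / cond$fs_Hz
  if (p > 1) stop("capture probability per step exceeds 1; lower k_cap or c_np")
  n <- round(cond$fs_Hz * cond$trace_length_s)
  m_ev <- round(cond$duration_ms / 1000 * cond$fs_Hz)
  n_eligible <- n - m_ev
  if (p == 0 || n_eligible < 1) return(empty_event_table())
  hit <- which(stats::runif(n_eligible) < p)
  k <- length(hit)
  if (k == 0) return(empty_event_table())
  t0 <- (hit - 1) / cond$fs_Hz
  data.frame(t_start_s = t0,
             t_end_s = t0 + cond$duration_ms / 1000,
             duration_ms = rep(cond$duration_ms, k),
             amplitude_nA = rep(amplitude_nA, k),
             rise_fraction = stats::runif(k, 0.2, 0.8))
}

#' Asymmetric-triangle pulse waveform
#'
#' Piecewise-linear rise from zero to the amplitude at
#' `rise_fraction * duration`, then linear fall back to zero. The apex
#' falls exactly on a sample so the maximum sample equals the amplitude.
#'
#' @param duration_ms Pulse width in ms (at least 2 samples at `fs_Hz`).
#' @param amplitude_nA Apex amplitude in nA.
#' @param rise_fraction Apex position as a fraction of the width, in (0, 1).
#' @param fs_Hz Sampling rate in Hz.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
spike_waveform <- function(duration_ms, amplitude_nA, rise_fraction, fs_Hz) {
  m <- round(duration_ms / 1000 * fs_Hz)
  if (m < 2) stop("degenerate event: duration shorter than 2 samples")
  p <- max(0L, min(m - 1L, as.integer(round(rise_fraction * (m - 1)))))
  k <- seq_len(m) - 1L
  up <- if (p == 0) rep(1, 1) else k[k <= p] / p
  down <- if (p == m - 1L) numeric(0) else (m - 1L - k[k > p]) / (m - 1L - p)
  amplitude_nA * c(up, down)
}

#' Synthesize colored Gaussian noise from a PSD
#'
#' Frequency-domain synthesis: independent complex Gaussian Fourier
#' coefficients with `E|Z_k|^2 = n * fs * S(f_k) / 2` on bins inside the
#' PSD band (DC and out-of-band bins zero), Hermitian-symmetrized and
#' inverse-transformed. With this one-sided scaling Parseval gives
#' `E[mean(y^2)] = sum_k S(f_k) * df`, i.e. the band-integrated PSD, so
#' the empirical RMS converges to [noise_rms()]. Marginal distribution is
#' exactly Gaussian with mean zero. Uses the current R RNG state.
#'
#' @param params A [noise_psd_params()].
#' @param n_samples Number of samples (>= 2).
#' @param fs_Hz Sampling rate in Hz.
#' @return Numeric vector of length `n_samples`.
#' @export
synth_colored_noise <- function(params, n_samples, fs_Hz) {
  stopifnot(inherits(params, "noise_psd_params"), n_samples >= 2)
  n <- as.integer(n_samples)
  nh <- n %/% 2L
  f <- (1:nh) * fs_Hz / n
  inband <- f >= params$f_min_Hz & f <= params$f_max_Hz
  S <- numeric(nh)
  S[inband] <- noise_psd(params, f[inband])
  v <- n * fs_Hz * S / 2          # E|Z_k|^2 per positive-frequency bin
  Z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) *
    sqrt(v / 2)
  if (n %% 2L == 0L) {            # real Nyquist bin, unpaired
    Z[nh] <- complex(real = stats::rnorm(1) * sqrt(v[nh]), imaginary = 0)
  }
  spec <- complex(real = numeric(n))
  spec[2:(nh + 1L)] <- Z
  idx <- n - (1:(nh - (1 - n %% 2L))) + 1L
  spec[idx] <- Conj(Z[seq_along(idx)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Synthesize a baseline with jumps and slow drift
#'
#' Open-pore level plus (a) randomly occurring signed steps that persist
#' (adsorption/desorption-like jumps) and (b) a slow drift equal to the
#' sum of eight sinusoidal terms (four sines, four cosines) with random
#' low frequencies and amplitudes. Uses the current R RNG state.
#'
#' @param n_samples Number of samples.
#' @param fs_Hz Sampling rate in Hz.
#' @param i0_nA Open-pore current in nA.
#' @param jump_cfg List with `rate_per_s` (expected jumps per second,
#'   default 0.05) and `amp_frac` (step amplitude drawn from
#'   Uniform(-amp_frac, amp_frac) of `i0`, default 0.02).
#' @param drift_cfg List with `n_terms` (total sinusoidal terms, default 8),
#'   `f_range` (Hz, default c(0.05, 2)) and `amp_frac` (per-term amplitude
#'   Uniform(0, amp_frac) of `i0`, default 0.005).
#' @return Numeric vector of length `n_samples`.
#' @export
synth_baseline <- function(n_samples, fs_Hz, i0_nA,
                           jump_cfg = list(), drift_cfg = list()) {
  jc <- utils::modifyList(list(rate_per_s = 0.05, amp_frac = 0.02), jump_cfg)
  dc <- utils::modifyList(list(n_terms = 8, f_range = c(0.05, 2),
                               amp_frac = 0.005), drift_cfg)
  n <- as.integer(n_samples)
  base <- rep(i0_nA, n)
  p <- jc$rate_per_s / fs_Hz
  if (p > 0 && jc$amp_frac > 0) {
    at <- which(stats::runif(n) < p)
    if (length(at)) {
      steps <- numeric(n)
      steps[at] <- stats::runif(length(at), -jc$amp_frac, jc$amp_frac) * i0_nA
      base <- base + cumsum(steps)
    }
  }
  if (dc$n_terms > 0 && dc$amp_frac > 0) {
    t <- (0:(n - 1L)) / fs_Hz
    freqs <- stats::runif(dc$n_terms, dc$f_range[1], dc$f_range[2])
    amps <- stats::runif(dc$n_terms, 0, dc$amp_frac) * i0_nA
    half <- dc$n_terms %/% 2
    for (j in seq_len(dc$n_terms)) {
      ph <- if (j <= half) sin(2 * pi * freqs[j] * t) else
        cos(2 * pi * freqs[j] * t)
      base <- base + amps[j] * ph
    }
  }
  base
}

#' Generate one labeled synthetic trace
#'
#' Composes the three parts of a synthetic recording: randomly placed
#' translocation pulses (subtracted from the baseline: blockades reduce
#' current), colored background noise scaled to the condition's SNR, and
#' baseline jumps plus slow drift. The clean trace is baseline minus
#' pulses, exactly; the noisy trace adds the scaled noise. Fully
#' reproducible from `seed`.
#'
#' @param cond A [sim_condition()].
#' @param seed Integer seed.
#' @param pore,elec,noise Physical models; see [pore_spec()],
#'   [electrolyte()], [noise_psd_params()].
#' @param p2p_factor RMS-to-peak-to-peak factor in the SNR definition.
#' @param k_cap Capture-rate constant (events/s/nM).
#' @param jump_cfg,drift_cfg Baseline configs, see [synth_baseline()].
#' @return An object of class `nanopore_trace`: list with `noisy`, `clean`,
#'   `fs_Hz`, `condition`, `seed`, `events` (event table), `i0_nA`,
#'   `amplitude_nA`, `noise_rms_nA` (calibrated RMS after scaling).
#' @export
generate_trace <- function(cond, seed, pore = pore_spec(),
                           elec = electrolyte(),
                           noise = noise_psd_params(),
                           p2p_factor = 6, k_cap = 20,
                           jump_cfg = list(), drift_cfg = list()) {
  stopifnot(inherits(cond, "sim_condition"))
  set.seed(as.integer(seed))
  n <- round(cond$fs_Hz * cond$trace_length_s)
  i0 <- open_pore_current(pore, elec, cond$bias_V)
  amp <- blockade_amplitude(pore, cond$d_np_nm, i0)
  base <- synth_baseline(n, cond$fs_Hz, i0, jump_cfg, drift_cfg)
  events <- sample_events(cond, amp, k_cap = k_cap)
  clean <- base
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      w <- spike_waveform(events$duration_ms[i], events$amplitude_nA[i],
                          events$rise_fraction[i], cond$fs_Hz)
      j0 <- round(events$t_start_s[i] * cond$fs_Hz) + 1L
      j1 <- min(n, j0 + length(w) - 1L)
      clean[j0:j1] <- clean[j0:j1] - w[seq_len(j1 - j0 + 1L)]
    }
  }
  base_rms <- noise_rms(noise)
  scale <- snr_noise_scale(snr_spec(cond$snr, p2p_factor), amp, base_rms)
  noisy <- clean
  if (scale > 0) noisy <- clean + scale * synth_colored_noise(noise, n, cond$fs_Hz)
  structure(list(noisy = noisy, clean = clean, fs_Hz = cond$fs_Hz,
                 condition = cond, seed = as.integer(seed), events = events,
                 i0_nA = i0, amplitude_nA = amp,
                 noise_rms_nA = scale * base_rms),
            class = "nanopore_trace")
}

#' @export
print.nanopore_trace <- function(x, ...) {
  cat(sprintf(paste0("<nanopore_trace> %.1f s @ %g Hz, %d events, ",
                     "I0 = %.3g nA, amp = %.3g nA, SNR = %g\n"),
              x$condition$trace_length_s, x$fs_Hz, nrow(x$events),
              x$i0_nA, x$amplitude_nA, x$condition$snr))
  invisible(x)
}

#' Full condition grid of the synthetic study
#'
#' 20 concentrations log-spaced over [0.01, 1] nM, 15 diameters 3..17 nm
#' in 1 nm steps, and 5 assigned durations (0.5, 1, 1.5, 3, 5 ms):
#' 1500 conditions.
#'
#' @return A `data.frame` with columns `c_np_nM`, `d_np_nm`, `duration_ms`.
#' @export
default_grid <- function() {
  expand.grid(c_np_nM = 10^seq(log10(0.01), log10(1), length.out = 20),
              d_np_nm = 3:17,
              duration_ms = c(0.5, 1, 1.5, 3, 5),
              KEEP.OUT.ATTRS = FALSE)
}

#' Generate a windowed train/validation/test dataset over a grid
#'
#' Iterates the condition grid round-robin, generating independent traces
#' per split until the requested number of 0.5 s windows is reached, then
#' labels every window from its trace's ground-truth event table. Window
#' counts are honored exactly (surplus windows are dropped).
#'
#' @param grid `data.frame` with columns `c_np_nM`, `d_np_nm`, `duration_ms`
#'   (see [default_grid()]); a scaled-down grid is fine.
#' @param snr Target SNR shared by the whole dataset.
#' @param windows_per_split Named integer vector, e.g.
#'   `c(train = 1500, val = 500, test = 500)`.
#' @param seed Master seed; per-trace seeds are derived deterministically.
#' @param window_s Window length in seconds.
#' @param trace_length_s Length of each generated trace.
#' @param dir Optional directory: if given, each trace is written as a bundle
#'   plus event-table TSV and the manifest records the paths.
#' @param ... Passed to [generate_trace()].
#' @return Object of class `bnet_dataset`: per split a list with `x`
#'   (windows x samples matrix) and `labels` (data.frame with `count`,
#'   `mean_amplitude_nA`, `mean_duration_ms` and condition columns), plus
#'   `manifest`, `window_s`, `fs_Hz`.
#' @export
generate_dataset <- function(grid, snr,
                             windows_per_split = c(train = 1500, val = 500,
                                                   test = 500),
                             seed = 1, window_s = 0.5, trace_length_s = 5,
                             dir = NULL, ...) {
  stopifnot(nrow(grid) >= 1, all(c("train", "val", "test") %in%
                                   names(windows_per_split)))
  fs <- if (!is.null(grid$fs_Hz)) grid$fs_Hz[1] else 10000
  wpt <- floor(trace_length_s / window_s)
  if (wpt < 1) stop("trace shorter than one window")
  set.seed(as.integer(seed))
  trace_seeds <- sample.int(.Machine$integer.max %/% 2, 100000L)
  out <- list()
  manifest <- list()
  sctr <- 0L
  for (split in c("train", "val", "test")) {
    need <- windows_per_split[[split]]
    n_traces <- ceiling(need / wpt)
    xs <- vector("list", n_traces)
    lb <- vector("list", n_traces)
    for (i in seq_len(n_traces)) {
      g <- grid[((i - 1L) %% nrow(grid)) + 1L, ]
      cond <- sim_condition(g$c_np_nM, g$d_np_nm, g$duration_ms, snr = snr,
                            trace_length_s = trace_length_s, fs_Hz = fs)
      sctr <- sctr + 1L
      tr <- generate_trace(cond, seed = trace_seeds[sctr], ...)
      seg <- segment_trace(tr, window_s = window_s)
      lab <- label_windows(seg, tr$events)
      lab$c_np_nM <- g$c_np_nM
      lab$d_np_nm <- g$d_np_nm
      lab$duration_ms <- g$duration_ms
      lab$snr <- snr
      xs[[i]] <- seg$x
      lb[[i]] <- lab
      path <- NA_character_
      if (!is.null(dir)) {
        path <- file.path(dir, sprintf("%s_trace_%04d.rds", split, i))
        write_bundle(tr, path)
      }
      manifest[[length(manifest) + 1L]] <-
        data.frame(split = split, trace = i, seed = trace_seeds[sctr],
                   c_np_nM = g$c_np_nM, d_np_nm = g$d_np_nm,
                   duration_ms = g$duration_ms, snr = snr, path = path)
    }
    x <- do.call(rbind, xs)[seq_len(need), , drop = FALSE]
    labels <- do.call(rbind, lb)[seq_len(need), , drop = FALSE]
    rownames(labels) <- NULL
    out[[split]] <- list(x = x, labels = labels)
  }
  structure(c(out, list(manifest = do.call(rbind, manifest),
                        window_s = window_s, fs_Hz = fs, snr = snr)),
            class = "bnet_dataset")
}
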