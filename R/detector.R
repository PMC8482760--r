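#' Threshold-detector configuration
#'
#' @param n_threshold Prominence threshold as a multiple of the
#'   background-noise RMS (the classic sweep uses 4..25).
#' @param min_separation_ms Peaks closer than this are suppressed
#'   (greedy non-maximum suppression in decreasing prominence order, which
#'   makes the detected count provably non-increasing in `n_threshold`).
#' @param width_rule Duration convention: `"half_prominence_x2"` (default;
#'   twice the full width at half prominence — exact for triangular
#'   pulses, whose half-height width is half the base) or `"fwhm"` (raw
#'   full width at half prominence).
#' @param detrend_ms Running-median window for baseline removal, in ms.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(n_threshold = 6, min_separation_ms = 0.3,
                            width_rule = c("half_prominence_x2", "fwhm"),
                            detrend_ms = 50) {
  stopifnot(n_threshold > 0, min_separation_ms >= 0, detrend_ms > 0)
  structure(list(n_threshold = n_threshold,
                 min_separation_ms = min_separation_ms,
                 width_rule = match.arg(width_rule),
                 detrend_ms = detrend_ms),
            class = "detector_config")
}

detrend_running_median <- function(x, fs, detrend_ms = 50) {
  k <- round(detrend_ms / 1000 * fs)
  k <- max(3L, k + (1L - k %% 2L))  # odd, >= 3
  if (k >= length(x)) return(x - stats::median(x))
  x - stats::runmed(x, k, endrule = "median")
}

#' Robust background-noise RMS estimate
#'
#' Median absolute deviation (scaled by 1.4826) of the running-median
#' detrended trace; insensitive to sparse translocation spikes and to
#' baseline jumps/drift. Returns 0 for a constant trace.
#'
#' @param trace_samples Numeric current vector (>= 1000 samples).
#' @param fs Sampling rate in Hz.
#' @param detrend_ms Running-median window in ms.
#' @return RMS estimate in the units of the input.
#' @export
estimate_noise_rms <- function(trace_samples, fs, detrend_ms = 50) {
  if (length(trace_samples) < 1000)
    stop("need at least 1000 samples for a noise estimate")
  d <- detrend_running_median(trace_samples, fs, detrend_ms)
  stats::mad(d, center = 0)
}

#' Detect translocation events by prominence threshold
#'
#' The trace is baseline-detrended with a running median, inverted
#' (blockades become positive peaks), and all local maxima with
#' topographic prominence of at least `n_threshold * rms` are kept.
#' Surviving peaks closer than `min_separation_ms` are reduced by greedy
#' non-maximum suppression (largest prominence wins). Event amplitude is
#' the peak's depth below the detrended baseline (prominence serves
#' only as the detection statistic: it is valley-referenced and
#' overestimates depth by the typical noise excursion); duration
#' follows the config's width rule.
#'
#' @param trace_samples Numeric current vector (nA).
#' @param fs Sampling rate in Hz.
#' @param cfg A [detector_config()].
#' @param rms Background-noise RMS; if `NULL`, estimated with
#'   [estimate_noise_rms()].
#' @return Object of class `detection`: list with `events` (data.frame
#'   `t_start_s`, `t_end_s`, `t_peak_s`, `duration_ms`, `amplitude_nA`,
#'   `frequency_Hz` — reciprocal interval to the next event, `NA` for the
#'   last), `rms`, `cfg`.
#' @export
detect_events <- function(trace_samples, fs, cfg = detector_config(),
                          rms = NULL) {
  stopifnot(inherits(cfg, "detector_config"))
  if (is.null(rms)) rms <- estimate_noise_rms(trace_samples, fs,
                                              cfg$detrend_ms)
  inv <- -detrend_running_median(trace_samples, fs, cfg$detrend_ms)
  pk <- cpp_find_peaks(inv)
  thr <- cfg$n_threshold * rms
  pk <- pk[pk$prominence >= thr & pk$prominence > 0, , drop = FALSE]
  # greedy NMS: process in decreasing prominence; monotone in threshold
  if (nrow(pk) > 1 && cfg$min_separation_ms > 0) {
    ord <- order(-pk$prominence, pk$idx)
    sep <- cfg$min_separation_ms / 1000 * fs
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(pk$idx[kept] - pk$idx[i]) >= sep))
        kept <- c(kept, i)
    }
    pk <- pk[sort(kept), , drop = FALSE]
  }
  wf <- if (cfg$width_rule == "half_prominence_x2") 2 else 1
  k <- nrow(pk)
  ev <- data.frame(
    t_start_s = (pk$idx - 1 - wf * (pk$idx - pk$left)) / fs,
    t_end_s = (pk$idx - 1 + wf * (pk$right - pk$idx)) / fs,
    t_peak_s = (pk$idx - 1) / fs,
    duration_ms = wf * pk$width_samples / fs * 1000,
    amplitude_nA = inv[pk$idx])
  ev$frequency_Hz <- if (k >= 2)
    c(1 / diff(ev$t_peak_s), NA_real_) else rep(NA_real_, k)
  structure(list(events = ev, rms = rms, cfg = cfg), class = "detection")
}

#' Per-trace summary of classic detector output
#'
#' Event frequency is the reciprocal of the interval between an event and
#' the immediately following one, so it is defined only when at least two
#' events were found; amplitude and duration need at least one.
#'
#' @param det A `detection` from [detect_events()].
#' @return One-row `data.frame`: `n_events`, `mean_frequency_Hz`,
#'   `mean_amplitude_nA`, `mean_duration_ms` (`NA` where undefined).
#' @export
classic_features <- function(det) {
  stopifnot(inherits(det, "detection"))
  ev <- det$events
  k <- nrow(ev)
  data.frame(
    n_events = k,
    mean_frequency_Hz = if (k >= 2)
      mean(ev$frequency_Hz, na.rm = TRUE) else NA_real_,
    mean_amplitude_nA = if (k >= 1) mean(ev$amplitude_nA) else NA_real_,
    mean_duration_ms = if (k >= 1) mean(ev$duration_ms) else NA_real_)
}

#' Sweep the prominence threshold
#'
#' Applies [detect_events()] for every threshold multiple in `n_values`
#' and summarizes each detection.
#'
#' @param trace_samples Numeric current vector.
#' @param fs Sampling rate in Hz.
#' @param n_values Threshold multiples (default 4..25).
#' @param cfg Base [detector_config()] (its `n_threshold` is overridden).
#' @param rms Noise RMS shared across the sweep; estimated once if `NULL`.
#' @return Tidy `data.frame`: one row per threshold with the
#'   [classic_features()] columns and `n_threshold`.
#' @export
threshold_sweep <- function(trace_samples, fs, n_values = 4:25,
                            cfg = detector_config(), rms = NULL) {
  if (is.null(rms)) rms <- estimate_noise_rms(trace_samples, fs,
                                              cfg$detrend_ms)
  rows <- lapply(n_values, function(n) {
    c2 <- cfg; c2$n_threshold <- n
    cbind(n_threshold = n,
          classic_features(detect_events(trace_samples, fs, c2, rms = rms)))
  })
  do.call(rbind, rows)
}
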