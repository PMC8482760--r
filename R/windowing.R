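#' Segment a trace into fixed temporal windows
#'
#' Consecutive, non-overlapping windows of `window_s` seconds; a trailing
#' partial window is dropped. Returns the noisy samples by default.
#'
#' @param trace A `nanopore_trace`.
#' @param window_s Window length in seconds (default 0.5).
#' @param use Which array to segment, `"noisy"` or `"clean"`.
#' @return Object of class `trace_windows`: list with `x` (windows x
#'   samples matrix), `t_start_s`, `window_s`, `fs_Hz`.
#' @export
segment_trace <- function(trace, window_s = 0.5, use = c("noisy", "clean")) {
  use <- match.arg(use)
  stopifnot(inherits(trace, "nanopore_trace"))
  v <- trace[[use]]
  wlen <- round(window_s * trace$fs_Hz)
  nw <- length(v) %/% wlen
  if (nw == 0) {
    warning("trace shorter than one window; returning no windows")
    return(structure(list(x = matrix(numeric(0), 0, wlen),
                          t_start_s = numeric(0), window_s = window_s,
                          fs_Hz = trace$fs_Hz), class = "trace_windows"))
  }
  x <- matrix(v[seq_len(nw * wlen)], nrow = nw, ncol = wlen, byrow = TRUE)
  structure(list(x = x, t_start_s = (seq_len(nw) - 1) * window_s,
                 window_s = window_s, fs_Hz = trace$fs_Hz),
            class = "trace_windows")
}

#' Label one temporal window from the ground-truth event table
#'
#' An event belongs to the window containing its temporal midpoint, so
#' every event is counted in exactly one window. Zero-event windows are
#' labeled (0, 0, 0).
#'
#' @param t0_s,t1_s Window extent `[t0, t1)` in seconds.
#' @param events Event table (`data.frame` sorted by `t_start_s`).
#' @return Named numeric vector `count`, `mean_amplitude_nA`,
#'   `mean_duration_ms`.
#' @export
label_window <- function(t0_s, t1_s, events) {
  if (nrow(events) == 0)
    return(c(count = 0, mean_amplitude_nA = 0, mean_duration_ms = 0))
  mid <- events$t_start_s + events$duration_ms / 2000
  sel <- mid >= t0_s & mid < t1_s
  k <- sum(sel)
  if (k == 0)
    return(c(count = 0, mean_amplitude_nA = 0, mean_duration_ms = 0))
  c(count = k,
    mean_amplitude_nA = mean(events$amplitude_nA[sel]),
    mean_duration_ms = mean(events$duration_ms[sel]))
}

#' Label every window of a segmented trace
#'
#' @param windows A `trace_windows` object from [segment_trace()].
#' @param events Ground-truth event table.
#' @return `data.frame` with one row per window: `count`,
#'   `mean_amplitude_nA`, `mean_duration_ms`.
#' @export
label_windows <- function(windows, events) {
  stopifnot(inherits(windows, "trace_windows"))
  out <- t(vapply(windows$t_start_s, function(t0)
    label_window(t0, t0 + windows$window_s, events), numeric(3)))
  as.data.frame(out)
}
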