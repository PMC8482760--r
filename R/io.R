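# Trace bundles are stored as version-tagged RDS containers (lossless for
# doubles); event tables and trace exports are tab-delimited text with a
# header row, '.' decimal, current in nA, time in s, duration in ms.

BUNDLE_FORMAT <- "bnet-trace-bundle"
BUNDLE_VERSION <- 1L

#' Write a trace bundle
#'
#' Serializes the noisy and clean arrays, sampling rate, generating
#' condition, seed and event table into a single container file. A
#' sibling `<path>.events.tsv` with the ground-truth event table is
#' written alongside.
#'
#' @param trace A `nanopore_trace`.
#' @param path Output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(trace, path) {
  stopifnot(inherits(trace, "nanopore_trace"))
  obj <- list(format = BUNDLE_FORMAT, version = BUNDLE_VERSION,
              noisy = trace$noisy, clean = trace$clean, fs_Hz = trace$fs_Hz,
              condition = unclass(trace$condition), seed = trace$seed,
              events = trace$events, i0_nA = trace$i0_nA,
              amplitude_nA = trace$amplitude_nA,
              noise_rms_nA = trace$noise_rms_nA)
  saveRDS(obj, path)
  write_event_table(trace$events, paste0(path, ".events.tsv"))
  invisible(path)
}

#' Read a trace bundle
#'
#' Fails with an explicit format error on anything that is not a bundle;
#' a bundle without the clean array is read successfully with
#' `has_clean = FALSE` attached.
#'
#' @param path Bundle file path.
#' @return A `nanopore_trace`.
#' @export
read_bundle <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable bundle: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, BUNDLE_FORMAT))
    stop("corrupted or foreign bundle: missing format tag '",
         BUNDLE_FORMAT, "'")
  if (!is.numeric(obj$version) || obj$version > BUNDLE_VERSION)
    stop("unsupported bundle version: ", obj$version)
  tr <- structure(list(noisy = obj$noisy, clean = obj$clean,
                       fs_Hz = obj$fs_Hz,
                       condition = structure(obj$condition,
                                             class = "sim_condition"),
                       seed = obj$seed, events = obj$events,
                       i0_nA = obj$i0_nA, amplitude_nA = obj$amplitude_nA,
                       noise_rms_nA = obj$noise_rms_nA),
                  class = "nanopore_trace")
  attr(tr, "has_clean") <- !is.null(obj$clean)
  tr
}

#' Write an event table as tab-delimited text
#'
#' Columns: `event_id`, `t_start_s`, `t_end_s`, `duration_ms`,
#' `amplitude_nA`.
#'
#' @param events Event table `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  out <- data.frame(event_id = seq_len(nrow(events)),
                    t_start_s = events$t_start_s,
                    t_end_s = events$t_end_s,
                    duration_ms = events$duration_ms,
                    amplitude_nA = events$amplitude_nA)
  utils::write.table(format(out, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table, checking its invariants
#'
#' @param path TSV path written by [write_event_table()].
#' @return Event table `data.frame` sorted by start time.
#' @export
read_event_table <- function(path) {
  ev <- utils::read.delim(path)
  need <- c("event_id", "t_start_s", "t_end_s", "duration_ms",
            "amplitude_nA")
  if (!all(need %in% names(ev))) stop("malformed event table: ", path)
  if (nrow(ev)) {
    if (is.unsorted(ev$t_start_s)) stop("event table not sorted by t_start_s")
    if (any(abs(ev$t_end_s - ev$t_start_s - ev$duration_ms / 1000) > 1e-9))
      stop("event table violates t_end - t_start = duration")
  }
  ev
}

#' Export a trace as delimited text
#'
#' @param trace A `nanopore_trace`.
#' @param path Output TSV path (columns `t_s`, `noisy_nA`, `clean_nA`).
#' @return `path`, invisibly.
#' @export
export_trace_tsv <- function(trace, path) {
  n <- length(trace$noisy)
  df <- data.frame(t_s = (seq_len(n) - 1) / trace$fs_Hz,
                   noisy_nA = trace$noisy, clean_nA = trace$clean)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a training checkpoint
#'
#' @param ckpt A `bnet_checkpoint`.
#' @param path File path.
#' @return `path` (write) or the checkpoint (read).
#' @export
write_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "bnet_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "bnet_checkpoint")) stop("not a checkpoint: ", path)
  ck
}
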