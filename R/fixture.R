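#' Miniature standard database
#'
#' Deterministic scaled-down analog of the full synthetic database: a
#' 2 x 2 x 2 condition grid (concentration, diameter, duration) at
#' SNR = 4, segmented into 60/30/30 train/validation/test windows of
#' 0.5 s. Builds in seconds on one CPU and is used as the shared fixture
#' across tests and examples.
#'
#' @param seed Master seed.
#' @param dir Optional directory; if given, trace bundles and event
#'   tables are written there.
#' @return A `bnet_dataset` (see [generate_dataset()]).
#' @export
make_fixture <- function(seed = 1, dir = NULL) {
  grid <- expand.grid(c_np_nM = c(0.1, 1), d_np_nm = c(8, 14),
                      duration_ms = c(1, 3), KEEP.OUT.ATTRS = FALSE)
  generate_dataset(grid, snr = 4,
                   windows_per_split = c(train = 60, val = 30, test = 30),
                   seed = seed, dir = dir)
}

#' Checksum of a dataset's labels
#'
#' MD5 of a canonical text rendering of all split labels; identical
#' across runs for a fixed seed.
#'
#' @param dataset A `bnet_dataset`.
#' @return Length-1 character MD5 digest.
#' @export
dataset_checksum <- function(dataset) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  lab <- do.call(rbind, lapply(c("train", "val", "test"), function(s) {
    l <- dataset[[s]]$labels
    l$split <- s
    l
  }))
  utils::write.table(format(lab, digits = 12), tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  unname(tools::md5sum(tmp))
}
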