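#' Relative error
#'
#' `|x - x0| / |x0|`. Not symmetric in its arguments. A zero true value
#' is a domain error here: zero-truth windows must be routed through the
#' zero rules of [window_errors()] instead.
#'
#' @param x Predicted values.
#' @param x0 True values (all non-zero).
#' @return Non-negative relative errors.
#' @export
relative_error <- function(x, x0) {
  if (any(x0 == 0)) stop("relative_error undefined for x0 = 0; use window_errors")
  abs(x - x0) / abs(x0)
}

#' Relative percent difference
#'
#' Symmetric, bounded error measure `2 |x - x0| / (|x| + |x0|)` in
#' [0, 2], with the 0/0 case defined as 0. Used for the count so empty
#' windows never divide by zero.
#'
#' @param x,x0 Values to compare (vectorized).
#' @return RPD values in [0, 2].
#' @export
rpd <- function(x, x0) {
  den <- abs(x) + abs(x0)
  out <- numeric(length(den))
  nz <- den > 0
  out[nz] <- 2 * abs(x - x0)[nz] / den[nz]
  out
}

#' Per-window errors with the zero-count rules
#'
#' For each window: if the true count is 0 and the (rounded) predicted
#' count is 0, all three features score 0 error; if the true count is 0
#' but the prediction is positive, all three score 100% (stored as 1.0);
#' otherwise each feature scores its plain relative error. No `NaN` can
#' leave this function.
#'
#' @param truth `data.frame`/list with `count`, `mean_amplitude_nA`,
#'   `mean_duration_ms`.
#' @param prediction Same columns; `count` is the rounded predicted count.
#' @return `data.frame` with columns `err_count`, `err_amplitude`,
#'   `err_duration` (relative scale; multiply by 100 for percent).
#' @export
window_errors <- function(truth, prediction) {
  n <- length(truth$count)
  ec <- ea <- ed <- numeric(n)
  zt <- truth$count == 0
  fp <- zt & prediction$count > 0
  ec[fp] <- 1; ea[fp] <- 1; ed[fp] <- 1
  pos <- !zt
  if (any(pos)) {
    ec[pos] <- relative_error(prediction$count[pos], truth$count[pos])
    ea[pos] <- relative_error(prediction$mean_amplitude_nA[pos],
                              truth$mean_amplitude_nA[pos])
    ed[pos] <- relative_error(prediction$mean_duration_ms[pos],
                              truth$mean_duration_ms[pos])
  }
  data.frame(err_count = ec, err_amplitude = ea, err_duration = ed)
}

pop_sd <- function(v) {
  m <- mean(v)
  sqrt(mean((v - m)^2))
}

#' Hierarchical error aggregation
#'
#' The evaluation pipeline aggregates per-window errors in three steps:
#' (1) mean and population STD per generating condition
#' (`c_np_nM` x `d_np_nm` x `duration_ms`); (2) for each duration, the
#' average over the concentration-diameter surface of the condition
#' means; (3) the total, the mean over the per-duration averages. Empty
#' groups are skipped with a warning.
#'
#' @param records `data.frame` with condition columns `c_np_nM`,
#'   `d_np_nm`, `duration_ms` and error columns `err_count`,
#'   `err_amplitude`, `err_duration`.
#' @return Object of class `aggregate_report`: list with `per_condition`,
#'   `per_duration` and `total` data.frames (mean and `sd_` columns per
#'   feature).
#' @export
aggregate_errors <- function(records) {
  feats <- c("err_count", "err_amplitude", "err_duration")
  stopifnot(all(c(feats, "c_np_nM", "d_np_nm", "duration_ms") %in%
                  names(records)))
  if (nrow(records) == 0) {
    warning("no records to aggregate")
    return(structure(list(per_condition = records[0, ],
                          per_duration = records[0, ], total = records[0, ]),
                     class = "aggregate_report"))
  }
  key <- interaction(records$c_np_nM, records$d_np_nm, records$duration_ms,
                     drop = TRUE)
  agg <- function(df, by) {
    means <- stats::aggregate(df[feats], by = by, FUN = mean)
    sds <- stats::aggregate(df[feats], by = by, FUN = pop_sd)
    names(sds)[names(sds) %in% feats] <- paste0("sd_", feats)
    merge(means, sds)
  }
  per_cond <- agg(records, records[c("c_np_nM", "d_np_nm", "duration_ms")])
  per_dur <- do.call(rbind, lapply(split(per_cond, per_cond$duration_ms),
    function(g) {
      out <- data.frame(duration_ms = g$duration_ms[1])
      for (f in feats) {
        out[[f]] <- mean(g[[f]])
        out[[paste0("sd_", f)]] <- pop_sd(g[[f]])
      }
      out
    }))
  rownames(per_dur) <- NULL
  total <- data.frame(t(vapply(feats, function(f) {
    c(mean = mean(per_dur[[f]]), sd = pop_sd(per_dur[[f]]))
  }, numeric(2))))
  total$feature <- sub("err_", "", feats)
  structure(list(per_condition = per_cond, per_duration = per_dur,
                 total = total[c("feature", "mean", "sd")]),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat("<aggregate_report> total average relative errors:\n")
  for (i in seq_len(nrow(x$total)))
    cat(sprintf("  %-10s %6.2f%%  (STD %.2f%%)\n", x$total$feature[i],
                100 * x$total$mean[i], 100 * x$total$sd[i]))
  invisible(x)
}

#' Evaluate a trained B-Net on the test split of a dataset
#'
#' Runs gated inference window by window, applies the zero rules, and
#' aggregates.
#'
#' @param ckpt1,ckpt2 Path-1 and path-2 checkpoints.
#' @param dataset A `bnet_dataset`; its `test` split is used.
#' @param window_s Window length in seconds.
#' @return List with `records` (per-window truth, prediction and errors)
#'   and `report` (an `aggregate_report`).
#' @export
evaluate_bnet <- function(ckpt1, ckpt2, dataset, window_s = 0.5) {
  stopifnot(inherits(dataset, "bnet_dataset"))
  lab <- dataset$test$labels
  pred <- bnet_predict(ckpt1, ckpt2, dataset$test$x, window_s = window_s)
  err <- window_errors(lab, pred)
  records <- cbind(lab[c("c_np_nM", "d_np_nm", "duration_ms")],
                   truth_count = lab$count,
                   truth_amplitude = lab$mean_amplitude_nA,
                   truth_duration = lab$mean_duration_ms,
                   pred, err)
  list(records = records, report = aggregate_errors(records))
}

#' Join B-Net and classic-sweep results into one comparison table
#'
#' Long format: one row per (condition, method, threshold); B-Net rows
#' carry `NA` for the threshold.
#'
#' @param bnet_results `data.frame` of per-condition B-Net summaries
#'   (must contain condition columns and feature/error columns).
#' @param sweep_results `data.frame` of per-condition classic summaries
#'   with an `n_threshold` column.
#' @return Combined `data.frame` with `method` and `n_threshold` columns.
#' @export
compare_report <- function(bnet_results, sweep_results) {
  b <- bnet_results
  b$method <- "bnet"
  b$n_threshold <- NA_real_
  s <- sweep_results
  s$method <- "classic"
  cols <- union(names(b), names(s))
  for (cn in setdiff(cols, names(b))) b[[cn]] <- NA
  for (cn in setdiff(cols, names(s))) s[[cn]] <- NA
  rbind(b[cols], s[cols])
}
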