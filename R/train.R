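#' Training schedule for one path
#'
#' Encodes the published regimes: for SNR in {4, 2, 1} a batch of 32
#' windows, initial learning rate 0.001 and a 90% learning-rate cut
#' (multiplier 0.1) every 10 epochs for path 1 and every 20 for path 2;
#' for SNR in {0.5, 0.25} a batch of 8 and a 20% cut (multiplier 0.8) at
#' the same cadences.
#'
#' @param snr SNR regime of the training data.
#' @param path_id 1 or 2 (sets the decay cadence).
#' @param n_epochs Number of epochs (60 full-scale; 15 is the desk-scale
#'   default used in tests).
#' @param momentum SGD momentum (not published; 0.95 converges reliably
#'   at desk-scale step counts).
#' @return An object of class `train_schedule`.
#' @export
train_schedule <- function(snr, path_id, n_epochs = 15, momentum = 0.95) {
  high <- snr >= 1
  structure(list(batch_size = if (high) 32L else 8L, lr0 = 0.001,
                 decay_multiplier = if (high) 0.1 else 0.8,
                 decay_every_epochs = if (path_id == 1) 10L else 20L,
                 n_epochs = as.integer(n_epochs), momentum = momentum,
                 snr_regime = if (high) "snr>=1" else "snr<1",
                 path_id = path_id),
            class = "train_schedule")
}

assemble_targets <- function(labels, path_id, scalers = NULL) {
  if (path_id == 1) {
    # counts are standardized like the path-2 targets so the stated
    # schedule (lr 0.001) converges at desk scale; the scaler travels in
    # the checkpoint and predictions are mapped back before rounding
    mu <- mean(labels$count)
    sd <- stats::sd(labels$count)
    if (!is.finite(sd) || sd <= 0) sd <- 1
    list(y = matrix((labels$count - mu) / sd, ncol = 1), mean = mu, sd = sd)
  } else {
    # amplitude and duration are strictly positive and heavily skewed
    # across the grid (amplitude ~ d_np^3 spans ~40x), while the
    # evaluation metric is relative: regress log targets so smooth-l1
    # distance matches relative error, then standardize
    y <- log(cbind(labels$mean_amplitude_nA, labels$mean_duration_ms))
    if (is.null(scalers)) {
      mu <- colMeans(y)
      sd <- apply(y, 2, stats::sd)
      sd[!is.finite(sd) | sd <= 0] <- 1
    } else {
      mu <- scalers$mean; sd <- scalers$sd
    }
    list(y = sweep(sweep(y, 2, mu, "-"), 2, sd, "/"), mean = mu, sd = sd)
  }
}

validate_path <- function(params, cfg, xval, auxval, labels, target_mean,
                          target_sd, batch = 64L) {
  ckpt <- list(params = params, cfg = cfg)
  out <- predict_in_batches(ckpt, xval, aux = auxval, batch = batch)
  if (cfg$path_id == 1) {
    # rounded predictions, as at evaluation time (raw RPD is
    # pathological on empty windows: any small positive scores 2)
    pred <- round_count(pmax(0, out[, 1] * target_sd + target_mean))
    mean(rpd(pred, labels$count))
  } else {
    pred <- exp(sweep(sweep(out, 2, target_sd, "*"), 2, target_mean, "+"))
    ea <- relative_error(pred[, 1], labels$mean_amplitude_nA)
    ed <- relative_error(pred[, 2], labels$mean_duration_ms)
    mean(c(mean(ea), mean(ed)))
  }
}

#' Train one path of the B-Net
#'
#' Smooth-l1 loss, SGD with momentum, step learning-rate decay per the
#' schedule. Path 2 trains only on windows containing at least one event
#' and is teacher-forced: the injected count is the ground truth, never a
#' path-1 prediction. After every epoch the model is scored on the
#' validation split -- mean RPD of the rounded count for path 1, mean of
#' the amplitude and duration relative errors (teacher-forced) for path 2
#' -- and the best-scoring parameters are retained in the checkpoint.
#'
#' @param path_id 1 (count) or 2 (amplitude + duration).
#' @param dataset A `bnet_dataset` from [generate_dataset()].
#' @param schedule A [train_schedule()].
#' @param seed Integer seed controlling initialization and shuffling.
#' @param cfg A [bnet_config()]; defaults to the full-width architecture
#'   for the dataset's window length.
#' @param ema_decay Per-step decay of the Polyak (exponential moving
#'   average) parameter copy used for validation and for the returned
#'   checkpoint; 0 disables averaging.
#' @param verbose Print per-epoch loss and validation metric.
#' @return Checkpoint: list with `params` (best epoch), `cfg`, `schedule`,
#'   `input_scale`, `target_mean`/`target_sd`, `best_metric`, `best_epoch`,
#'   `history` (per-epoch data.frame), `seed`.
#' @export
train_path <- function(path_id, dataset, schedule = NULL, seed = 1,
                       cfg = NULL, ema_decay = 0.99, verbose = FALSE) {
  stopifnot(inherits(dataset, "bnet_dataset"))
  if (is.null(schedule)) schedule <- train_schedule(dataset$snr, path_id)
  if (is.null(cfg))
    cfg <- bnet_config(path_id,
                       window_len_samples = ncol(dataset$train$x))
  stopifnot(cfg$path_id == path_id)
  xtr <- dataset$train$x
  ltr <- dataset$train$labels
  xva <- dataset$val$x
  lva <- dataset$val$labels
  if (path_id == 2) {
    keep <- ltr$count >= 1
    if (!any(keep)) stop("path 2 requires event-containing training windows")
    xtr <- xtr[keep, , drop = FALSE]; ltr <- ltr[keep, , drop = FALSE]
    kv <- lva$count >= 1
    xva <- xva[kv, , drop = FALSE]; lva <- lva[kv, , drop = FALSE]
    stopifnot(all(ltr$count >= 1))   # loader contract: no empty windows
  }
  str_ <- standardize_windows(xtr)
  sva_ <- standardize_windows(xva)
  xtr <- str_$x
  xva <- sva_$x
  # auxiliary head inputs (path 2): ground-truth count (teacher forcing)
  # and the log of the window's robust scale, standardized by training
  # statistics -- log targets make log(amplitude) affine in log(scale)
  aux_mean <- mean(log(str_$scale))
  aux_sd <- stats::sd(log(str_$scale))
  if (!is.finite(aux_sd) || aux_sd <= 0) aux_sd <- 1
  auxtr <- auxva <- NULL
  if (path_id == 2) {
    auxtr <- cbind(ltr$count, (log(str_$scale) - aux_mean) / aux_sd)
    auxva <- cbind(lva$count, (log(sva_$scale) - aux_mean) / aux_sd)
  }
  tg <- assemble_targets(ltr, path_id)
  params <- bnet_params_init(cfg, seed)
  params$featnorm <- compute_featnorm(params, cfg, xtr)
  vel <- sgd_init(params)
  ema <- sgd_init(params)   # zero accumulators; bias-corrected on read
  ema_t <- 0L
  n <- nrow(xtr)
  best <- list(metric = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), val_metric = numeric(0))
  for (ep in seq_len(schedule$n_epochs)) {
    lr <- schedule$lr0 *
      schedule$decay_multiplier^((ep - 1) %/% schedule$decay_every_epochs)
    ord <- sample.int(n)
    tot <- 0; nb <- 0
    i <- 1L
    while (i <= n) {
      j <- min(n, i + schedule$batch_size - 1L)
      idx <- ord[i:j]
      xb <- xtr[idx, , drop = FALSE]
      yb <- tg$y[idx, , drop = FALSE]
      ab <- if (path_id == 2) auxtr[idx, , drop = FALSE] else NULL
      fwd <- bnet_forward(params, cfg, xb, aux = ab, keep_cache = TRUE)
      loss <- mean(rowSums(smooth_l1(fwd$out, yb)))
      gout <- smooth_l1_grad(fwd$out, yb) / nrow(xb)
      grads <- clip_grads(bnet_backward(params, cfg, fwd, gout), 5)
      upd <- sgd_step(params, grads, vel, lr, schedule$momentum)
      params <- upd$p; vel <- upd$v
      if (ema_decay > 0) {
        ema <- ema_update(ema, params, ema_decay)
        ema_t <- ema_t + 1L
      }
      tot <- tot + loss; nb <- nb + 1
      i <- j + 1L
    }
    cand <- if (ema_decay > 0) ema_read(ema, ema_decay, ema_t) else params
    cand$featnorm <- params$featnorm   # buffers are not averaged
    vm <- validate_path(cand, cfg, xva, auxva, lva, tg$mean, tg$sd)
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                   train_loss = tot / nb, val_metric = vm))
    if (vm < best$metric) best <- list(metric = vm, params = cand,
                                       epoch = ep)
    if (verbose)
      message(sprintf("epoch %2d  lr %.2g  loss %.4f  val %.4f",
                      ep, lr, tot / nb, vm))
  }
  structure(list(params = best$params, cfg = cfg, schedule = schedule,
                 input_norm = "per-window", aux_mean = aux_mean,
                 aux_sd = aux_sd, target_mean = tg$mean,
                 target_sd = tg$sd, best_metric = best$metric,
                 best_epoch = best$epoch, history = hist,
                 seed = as.integer(seed)),
            class = "bnet_checkpoint")
}

#' @export
print.bnet_checkpoint <- function(x, ...) {
  cat(sprintf(paste0("<bnet_checkpoint> path %d, width %d, best epoch %d",
                     " (val metric %.4g), %d epochs\n"),
              x$cfg$path_id, x$cfg$base_width, x$best_epoch, x$best_metric,
              nrow(x$history)))
  invisible(x)
}
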