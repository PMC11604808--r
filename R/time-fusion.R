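days_in_month <- function(year, month0) {
  # month0 in 0..11
  dim <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month0 + 1]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(month0 == 1 & leap, 29, dim)
}

#' Encode the nine time-information values for minutes
#'
#' Four cyclic pairs — hour of day (24-h cycle), day of month (fixed
#' 31-day cycle), month of year (12-month cycle) and day of week (7-day
#' cycle) — plus the log of the minutes since the last seizure. For
#' each cycle the first value is the calendar position (unit index
#' including the minute fraction, scaled to \[0, 5\]) and the second is
#' the time elapsed since the cycle start (scaled to \[0, 5\]); both
#' are computed at 1-min resolution, so every minute has a unique
#' encoding. The ninth value is `ln(1 + minutes since last seizure of
#' any kind)`, capped at `ln(1 + cap_minutes)`, the cap also standing
#' in when no seizure precedes the minute.
#'
#' @param minutes integer minute indices.
#' @param catalog a `seizure_catalog` (all seizures, not only leads).
#' @param epoch calendar origin of the recording clock.
#' @param cap_minutes cap for the ninth value (default 60 days).
#' @return numeric matrix `length(minutes) x 9`, columns
#'   `hour1, hour2, dom1, dom2, month1, month2, dow1, dow2, log_since`.
#' @export
encode_time_features <- function(minutes, catalog, epoch = DEFAULT_EPOCH,
                                 cap_minutes = 60 * 24 * 60) {
  tm <- minute_time(minutes, epoch)
  lt <- as.POSIXlt(tm, tz = "UTC")
  mod <- lt$hour * 60 + lt$min                     # minute of day
  hour_v <- mod / 1440 * 5
  dom_min <- (lt$mday - 1) * 1440 + mod            # minutes since month start
  dom_v <- dom_min / (31 * 1440) * 5
  dim_m <- days_in_month(lt$year + 1900, lt$mon)
  month1 <- (lt$mon + dom_min / (dim_m * 1440)) / 12 * 5
  year_start <- as.POSIXct(sprintf("%d-01-01", lt$year + 1900), tz = "UTC")
  year_days <- ifelse((lt$year + 1900) %% 4 == 0 &
                        ((lt$year + 1900) %% 100 != 0 |
                           (lt$year + 1900) %% 400 == 0), 366, 365)
  year_min <- as.numeric(difftime(tm, year_start, units = "mins"))
  month2 <- year_min / (year_days * 1440) * 5
  dow <- (lt$wday + 6) %% 7                        # Monday = 0
  dow_v <- (dow * 1440 + mod) / (7 * 1440) * 5
  since <- vapply(minutes, function(m) {
    prev <- catalog$onsets[catalog$onsets <= m]
    if (length(prev)) m - prev[length(prev)] else cap_minutes
  }, numeric(1))
  since <- pmin(since, cap_minutes)
  out <- cbind(hour1 = hour_v, hour2 = hour_v, dom1 = dom_v, dom2 = dom_v,
               month1 = month1, month2 = month2, dow1 = dow_v, dow2 = dow_v,
               log_since = log1p(since))
  rownames(out) <- NULL
  out
}

#' Configuration of the dense fusion classifier
#'
#' Two dense sigmoid layers separated by a dropout layer: the hidden
#' layer has exactly 10x the number of labels, the output one unit per
#' label; Adam at learning rate 1e-4 with mean-squared-error loss.
#'
#' @param n_labels number of labels.
#' @param dropout dropout fraction between the layers.
#' @param learning_rate,epochs,batch_size,patience,validation_fraction
#'   training loop controls.
#' @param seed integer seed.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(n_labels, dropout = 0.25,
                              learning_rate = 1e-4, epochs = 200,
                              batch_size = 32, patience = 20,
                              validation_fraction = 0.1, seed = 1) {
  stopifnot(n_labels >= 2, dropout >= 0, dropout < 1)
  structure(list(n_labels = as.integer(n_labels),
                 hidden_units = 10L * as.integer(n_labels),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build (initialize) the fusion classifier
#'
#' @param config a `classifier_config`.
#' @param input_width classifier input width: 5 LSTM output vectors
#'   plus the nine time values, i.e. `5 * n_labels + 9` in the standard
#'   pipeline.
#' @return an object of class `fusion_classifier` with a structure
#'   report (`structure`): two dense layers separated by one dropout
#'   layer.
#' @export
build_classifier <- function(config, input_width) {
  stopifnot(inherits(config, "classifier_config"), input_width >= 1)
  set.seed(config$seed)
  h <- config$hidden_units
  k <- config$n_labels
  structure(list(
    W1 = glorot(input_width, h), b1 = matrix(0, 1, h),
    W2 = glorot(h, k), b2 = matrix(0, 1, k),
    config = config, input_width = as.integer(input_width),
    structure = data.frame(
      kind = c("dense", "dropout", "dense"),
      units = c(h, h, k)),
    history = NULL),
    class = "fusion_classifier")
}

#' @export
print.fusion_classifier <- function(x, ...) {
  cat(sprintf("fusion classifier: %d -> %d (dropout %.2f) -> %d\n",
              x$input_width, x$config$hidden_units, x$config$dropout,
              x$config$n_labels))
  invisible(x)
}

clf_forward <- function(clf, x, drop_mask = NULL) {
  hraw <- stats::plogis(sweep(x %*% clf$W1, 2, clf$b1, `+`))
  h <- if (!is.null(drop_mask)) hraw * drop_mask else hraw
  y <- stats::plogis(sweep(h %*% clf$W2, 2, clf$b2, `+`))
  list(hraw = hraw, h = h, y = y)
}

adam_update <- function(par, grad, state, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1
  for (k in names(par)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grad[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grad[[k]]^2
    mhat <- state$m[[k]] / (1 - b1^state$t)
    vhat <- state$v[[k]] / (1 - b2^state$t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Train the fusion classifier
#'
#' One-hot targets under mean-squared error, Adam optimization,
#' inverted dropout between the layers, early stopping on a held-out
#' slice. Deterministic for a fixed seed.
#'
#' @param clf a `fusion_classifier`.
#' @param x input matrix (rows = minutes).
#' @param labels integer labels in `0:(n_labels-1)`.
#' @param verbose print per-epoch losses.
#' @return the trained classifier with a `history` element.
#' @export
train_classifier <- function(clf, x, labels, verbose = FALSE) {
  stopifnot(inherits(clf, "fusion_classifier"), nrow(x) == length(labels),
            ncol(x) == clf$input_width)
  cfg <- clf$config
  y <- one_hot(as.integer(labels), cfg$n_labels)
  set.seed(cfg$seed)
  n <- nrow(x)
  n_val <- max(1L, floor(cfg$validation_fraction * n))
  val_idx <- sample(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx, , drop = FALSE]
  xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx, , drop = FALSE]

  par <- clf[c("W1", "b1", "W2", "b2")]
  st <- list(t = 0,
             m = lapply(par, function(p) p * 0),
             v = lapply(par, function(p) p * 0))
  keep <- 1 - cfg$dropout
  best_val <- Inf; best_par <- par; since <- 0
  tl <- vl <- numeric(0)
  for (e in seq_len(cfg$epochs)) {
    perm <- sample(nrow(xt))
    eloss <- 0
    for (start in seq(1, nrow(xt), by = cfg$batch_size)) {
      sel <- perm[start:min(start + cfg$batch_size - 1, nrow(xt))]
      xb <- xt[sel, , drop = FALSE]; yb <- yt[sel, , drop = FALSE]
      mask <- if (cfg$dropout > 0)
        matrix((stats::runif(length(sel) * cfg$hidden_units) >= cfg$dropout) / keep,
               length(sel), cfg$hidden_units) else NULL
      fw <- clf_forward(list(W1 = par$W1, b1 = par$b1, W2 = par$W2,
                             b2 = par$b2), xb, mask)
      dy <- 2 * (fw$y - yb) / length(fw$y)
      dz2 <- dy * fw$y * (1 - fw$y)
      gW2 <- t(fw$h) %*% dz2
      gb2 <- matrix(colSums(dz2), 1)
      dh <- dz2 %*% t(par$W2)
      if (!is.null(mask)) dh <- dh * mask
      dz1 <- dh * fw$hraw * (1 - fw$hraw)
      gW1 <- t(xb) %*% dz1
      gb1 <- matrix(colSums(dz1), 1)
      upd <- adam_update(par, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                         st, cfg$learning_rate)
      par <- upd$par; st <- upd$state
      eloss <- eloss + mean((fw$y - yb)^2) * length(sel)
    }
    tl <- c(tl, eloss / nrow(xt))
    fv <- clf_forward(par, xv)
    vloss <- mean((fv$y - yv)^2)
    vl <- c(vl, vloss)
    if (verbose) message(sprintf("epoch %d train %.5f val %.5f", e,
                                 tl[e], vloss))
    if (vloss < best_val - 1e-7) {
      best_val <- vloss; best_par <- par; since <- 0
    } else if ((since <- since + 1) >= cfg$patience) break
  }
  clf[names(best_par)] <- best_par
  clf$history <- list(train_loss = tl, val_loss = vl, best_val = best_val)
  clf
}

#' @rdname train_classifier
#' @return `predict_classifier`: matrix of per-label sigmoid scores.
#' @export
predict_classifier <- function(clf, x) {
  stopifnot(inherits(clf, "fusion_classifier"), ncol(x) == clf$input_width)
  clf_forward(clf, x)$y
}

#' Cache per-minute LSTM outputs
#'
#' Runs the trained LSTM over the five test-convention segments of each
#' minute and stores the five concatenated output vectors — the
#' expensive half of the model, computed once so the fusion classifier
#' can be (re)trained in minutes.
#'
#' @param model a trained `lstm_model`.
#' @param minutes integer minute indices.
#' @param fetch_minute function(minute) returning the normalized
#'   `minute_record`.
#' @param duration segment duration in seconds.
#' @return list with `minutes` and `lstm_out` (matrix
#'   `n x (5 * n_labels)`).
#' @export
cache_lstm_outputs <- function(model, minutes, fetch_minute, duration = 10) {
  starts <- test_segment_starts(duration)
  k <- model$config$n_labels
  out <- matrix(NA_real_, length(minutes), 5 * k)
  # batch all segments of a block of minutes into one forward pass
  block <- 200L
  for (b0 in seq(1, length(minutes), by = block)) {
    idx <- b0:min(b0 + block - 1L, length(minutes))
    segs <- NULL
    for (j in seq_along(idx)) {
      rec <- fetch_minute(minutes[idx[j]])
      sl <- extract_segments(rec, starts, duration)
      if (is.null(segs))
        segs <- array(0, c(length(idx) * 5, nrow(sl[[1]]$data),
                           ncol(sl[[1]]$data)))
      for (s in 1:5) segs[(j - 1) * 5 + s, , ] <- sl[[s]]$data
    }
    pred <- predict_segment(model, segs)
    for (j in seq_along(idx))
      out[idx[j], ] <- as.vector(t(pred[(j - 1) * 5 + 1:5, , drop = FALSE]))
  }
  list(minutes = minutes, lstm_out = out)
}

#' Assemble classifier inputs from cached LSTM outputs and time features
#'
#' @param cached result of [cache_lstm_outputs()].
#' @param catalog a `seizure_catalog`.
#' @param epoch calendar origin.
#' @return matrix `n x (5 * n_labels + 9)`.
#' @export
classifier_inputs <- function(cached, catalog, epoch = DEFAULT_EPOCH) {
  cbind(cached$lstm_out,
        encode_time_features(cached$minutes, catalog, epoch))
}

#' Per-minute prediction: five LSTM outputs fused with time information
#'
#' Screens the minute, runs the LSTM on its five test-convention
#' segments, concatenates the outputs with the nine time values, and
#' passes them through the fusion classifier. The predicted label is
#' the argmax score (lowest index on ties).
#'
#' @param model a trained `lstm_model`.
#' @param clf a trained `fusion_classifier`.
#' @param record a normalized `minute_record`.
#' @param catalog a `seizure_catalog`.
#' @param epoch calendar origin.
#' @return list with `scores` (length `n_labels`) and `label`, or
#'   `NULL` (with a message) if the minute fails screening.
#' @export
predict_minute <- function(model, clf, record, catalog,
                           epoch = DEFAULT_EPOCH) {
  if (!isTRUE(c(screen_minute(record)))) {
    message(sprintf("minute %d fails the missing-data screen; no prediction",
                    record$start_minute))
    return(NULL)
  }
  dur <- model$input_shape[1] / record$sample_rate
  cached <- cache_lstm_outputs(model, record$start_minute,
                               function(m) record, dur)
  xin <- classifier_inputs(cached, catalog, epoch)
  scores <- drop(predict_classifier(clf, xin))
  list(scores = scores, label = which.max(scores) - 1L)
}

#' Retrain only the fusion classifier against new labels
#'
#' The LSTM parameters stay frozen: the classifier is retrained on the
#' cached LSTM outputs plus time features under a new paradigm's
#' labels (e.g. pre-ictal redefined as 40-80 min before seizure),
#' which takes minutes rather than the hours of LSTM training.
#'
#' @param cached result of [cache_lstm_outputs()] over training
#'   minutes.
#' @param paradigm the new `paradigm_spec`.
#' @param catalog a `seizure_catalog` with lead flags.
#' @param config a `classifier_config` sized for the new label count.
#' @param epoch calendar origin.
#' @return list with the trained `classifier` and `used` (data.frame
#'   of the minutes/labels actually used).
#' @export
retarget_classifier <- function(cached, paradigm, catalog, config,
                                epoch = DEFAULT_EPOCH) {
  stopifnot(inherits(paradigm, "paradigm_spec"),
            config$n_labels == paradigm$n_labels)
  lab <- label_minutes(cached$minutes, catalog, paradigm)
  keep <- !is.na(lab)
  if (!any(keep)) stop("no cached minute is labelable under the new paradigm")
  sub <- list(minutes = cached$minutes[keep],
              lstm_out = cached$lstm_out[keep, , drop = FALSE])
  xin <- classifier_inputs(sub, catalog, epoch)
  bal <- build_classifier_train_set(xin, lab[keep], seed = config$seed)
  clf <- build_classifier(config, ncol(xin))
  clf <- train_classifier(clf, bal$x, bal$labels)
  list(classifier = clf,
       used = data.frame(minute = sub$minutes, label = lab[keep]))
}
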