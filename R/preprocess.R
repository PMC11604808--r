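#' Rolling per-electrode normalization state
#'
#' Holds one amplitude standard deviation per electrode per day over a
#' trailing window of `window_days` days. The normalization divisor for
#' a minute is the mean of the stored daily SDs of its electrode,
#' recomputed once per day — so the divisor reflects amplitude across
#' brain states over many days rather than the minute itself.
#'
#' @param n_channels number of electrodes.
#' @param window_days trailing window length in days (default 30).
#' @return an object of class `normalization_state`.
#' @export
normalization_state <- function(n_channels, window_days = 30) {
  structure(list(n_channels = as.integer(n_channels),
                 window_days = as.integer(window_days),
                 days = integer(),
                 daily_sd = matrix(numeric(), 0, n_channels)),
            class = "normalization_state")
}

#' @export
print.normalization_state <- function(x, ...) {
  cat(sprintf("normalization_state: %d electrodes, %d/%d days stored\n",
              x$n_channels, length(x$days), x$window_days))
  invisible(x)
}

#' Append one day of records to the normalization state
#'
#' Computes the per-electrode SD over the concatenated non-missing
#' samples of the day, appends it, and evicts entries older than the
#' window. A day with zero non-missing samples on every electrode adds
#' no entry (with a warning).
#'
#' @param state a `normalization_state`.
#' @param day_records list of `minute_record`s, all from one calendar
#'   day.
#' @return the updated `normalization_state`.
#' @export
update_normalization <- function(state, day_records) {
  stopifnot(inherits(state, "normalization_state"), length(day_records) > 0)
  day <- day_records[[1]]$start_minute %/% 1440
  if (!all(vapply(day_records, function(r) r$start_minute %/% 1440, 0) == day))
    stop("records must all belong to one calendar day")
  sums <- rep(0, state$n_channels); sq <- rep(0, state$n_channels)
  n <- rep(0, state$n_channels)
  for (r in day_records) {
    ok <- !r$missing_mask
    x <- r$data
    x[!ok] <- 0
    sums <- sums + rowSums(x)
    sq <- sq + rowSums(x^2)
    n <- n + rowSums(ok)
  }
  if (all(n == 0)) {
    warning(sprintf("day %d has no non-missing samples; no entry appended", day))
    return(state)
  }
  sd_day <- sqrt(pmax(0, sq / pmax(n, 1) - (sums / pmax(n, 1))^2))
  sd_day[n == 0] <- NA_real_
  state$days <- c(state$days, day)
  state$daily_sd <- rbind(state$daily_sd, unname(sd_day))
  dimnames(state$daily_sd) <- NULL
  keep <- state$days > day - state$window_days
  state$days <- state$days[keep]
  state$daily_sd <- state$daily_sd[keep, , drop = FALSE]
  state
}

#' Per-electrode normalization divisor
#'
#' Mean of the stored daily SDs per electrode; electrodes whose mean is
#' zero (or with no history) are flagged degenerate with `NA`.
#'
#' @param state a `normalization_state`.
#' @return numeric vector of length `n_channels`; `NA` marks a
#'   degenerate divisor.
#' @export
normalization_divisor <- function(state) {
  if (length(state$days) == 0) return(rep(NA_real_, state$n_channels))
  d <- colMeans(state$daily_sd, na.rm = TRUE)
  d[!is.finite(d) | d == 0] <- NA_real_
  d
}

#' Normalize one minute of EEG
#'
#' Per electrode: missing samples are first replaced by the mean of the
#' electrode's non-missing samples in this minute (so they become
#' exactly zero after centering), then the minute mean is subtracted and
#' the result divided by the rolling divisor. Cold start: with no stored
#' history the current minute's own SD is used as divisor. The missing
#' mask is preserved.
#'
#' @param record a `minute_record`.
#' @param state a `normalization_state` (or `NULL` for pure cold start).
#' @return the normalized `minute_record`, with attribute `"usable"`
#'   set to `FALSE` if any electrode's divisor was degenerate.
#' @export
normalize_minute <- function(record, state = NULL) {
  stopifnot(inherits(record, "minute_record"))
  data <- record$data
  mask <- record$missing_mask
  nch <- nrow(data)
  cold <- is.null(state) || length(state$days) == 0
  divisor <- if (!cold) normalization_divisor(state) else rep(NA_real_, nch)
  usable <- TRUE
  for (ch in seq_len(nch)) {
    ok <- !mask[ch, ]
    mu <- if (any(ok)) mean(data[ch, ok]) else 0
    x <- data[ch, ]
    x[!ok] <- mu
    x <- x - mu
    d <- if (cold) {
      if (sum(ok) > 1) stats::sd(data[ch, ok]) else 0
    } else divisor[ch]
    if (is.na(d) || !is.finite(d) || d == 0) {
      usable <- FALSE                     # degenerate divisor
      d <- 1
    }
    data[ch, ] <- x / d
  }
  out <- minute_record(record$start_minute, data, record$sample_rate, mask)
  attr(out, "usable") <- usable
  out
}

#' Missing-data screen for one minute
#'
#' A minute is dropped when any electrode is missing more than one
#' second of samples (strictly more than `round(sample_rate)` samples —
#' 400 NaNs at 400 Hz); small telemetry dropouts are kept.
#'
#' @param record a `minute_record`.
#' @return `TRUE` to keep, `FALSE` to drop; on drop the attribute
#'   `"reason"` states the worst electrode's missing count.
#' @export
screen_minute <- function(record) {
  stopifnot(inherits(record, "minute_record"))
  worst <- max(rowSums(record$missing_mask))
  threshold <- round(record$sample_rate)   # 1 s of samples
  keep <- worst <= threshold
  if (!keep)
    attr(keep, "reason") <- sprintf("electrode with %d missing samples (> %d)",
                                    worst, threshold)
  keep
}

#' Cut fixed-duration segments out of a minute
#'
#' Sample values are copied exactly — no resampling or filtering; this
#' is the only segmentation the pipeline performs.
#'
#' @param record a (normalized, screened) `minute_record`.
#' @param starts segment start offsets in seconds within the minute.
#' @param duration segment duration in seconds (default 10).
#' @return list of `eeg_segment` objects: each has `start_minute`,
#'   `start_offset` (s), `duration` (s) and `data` (channels x samples).
#' @export
extract_segments <- function(record, starts, duration = 10) {
  stopifnot(inherits(record, "minute_record"))
  if (any(starts < 0 | starts + duration > 60))
    stop("segment start + duration must lie within the minute")
  rate <- record$sample_rate
  nsamp <- round(duration * rate)
  lapply(starts, function(s) {
    i0 <- round(s * rate) + 1
    structure(list(start_minute = record$start_minute, start_offset = s,
                   duration = duration,
                   data = record$data[, i0:(i0 + nsamp - 1), drop = FALSE]),
              class = "eeg_segment")
  })
}

#' Test-set segmentation convention
#'
#' Five non-overlapping segments per minute, starting at offsets 0, d,
#' 2d, 3d, 4d. With 10-s segments this is 0-10 s, ..., 40-50 s: a sixth
#' would require overlap on devices whose true rate sits just below
#' nominal, so five is the convention throughout.
#'
#' @param duration segment duration in seconds.
#' @return numeric vector of 5 start offsets.
#' @export
test_segment_starts <- function(duration = 10) {
  seq(0, by = duration, length.out = 5)
}

#' Checkpoint the normalization state as CSV
#'
#' @param state a `normalization_state`.
#' @param path CSV path (columns: day, one SD column per electrode).
#' @export
write_normalization_state <- function(state, path) {
  df <- data.frame(day = state$days)
  sds <- as.data.frame(state$daily_sd)
  names(sds) <- paste0("sd_ch", seq_len(state$n_channels))
  utils::write.csv(cbind(df, sds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normalization_state
#' @param n_channels,window_days as in [normalization_state()].
#' @export
read_normalization_state <- function(path, window_days = 30) {
  df <- utils::read.csv(path)
  nch <- ncol(df) - 1L
  st <- normalization_state(nch, window_days)
  st$days <- as.integer(df$day)
  st$daily_sd <- as.matrix(df[, -1, drop = FALSE])
  dimnames(st$daily_sd) <- NULL
  st
}
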