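#' Configuration for the synthetic long-term iEEG generator
#'
#' Emulates the regime of chronic implanted recordings: months of
#' continuous multi-channel signal stored as 1-min records, seizures
#' clustered on circadian/weekly/multidien cycles, a pre-ictal signature
#' in a configurable window before each onset, telemetry dropouts
#' (missing-sample blocks) and slow multiplicative amplitude drift.
#'
#' The background is, per channel, an AR(1) process (pole `ar_pole`)
#' plus unit white noise, with a log-normal random-walk amplitude drift.
#' The pre-ictal signature is one of:
#' \describe{
#'   \item{marker}{a half-sine pulse of `marker_duration_ms` added to
#'     all channels, inserted with probability `marker_rate_per_s` per
#'     second at a uniform offset — the detectability-validation signal;}
#'   \item{variance_ramp}{channel amplitude scaled linearly from 1 up to
#'     `preictal_scale` toward onset;}
#'   \item{autocorr_ramp}{the AR pole moved linearly from `ar_pole`
#'     toward `autocorr_pole_max` toward onset.}
#' }
#'
#' @param n_channels number of electrodes (>= 1).
#' @param sample_rate sampling rate in Hz.
#' @param duration_days recording length in days (may be fractional).
#' @param seizure_rate Poisson base rate, seizures/day.
#' @param cycle_weights named numeric vector: names are cycle periods in
#'   hours (e.g. `"24"`, `"168"`), values are modulation amplitudes in
#'   \[0, 1\].
#' @param preictal_mode `"marker"`, `"variance_ramp"` or
#'   `"autocorr_ramp"`.
#' @param preictal_horizon minutes before onset where the signature is
#'   active: a scalar `h` means the window `[1, h]` minutes-to-onset; a
#'   length-2 vector `c(lo, hi)` means `lo <= minutes-to-onset < hi`.
#' @param marker_duration_ms marker pulse duration (>= 1 sample).
#' @param marker_rate_per_s per-second insertion probability inside the
#'   pre-ictal window.
#' @param marker_amplitude absolute pulse amplitude; default 5x the
#'   theoretical background SD (detectable, not saturating).
#' @param preictal_scale amplitude factor reached at onset in
#'   `variance_ramp` mode.
#' @param ar_pole,autocorr_pole_max background AR(1) pole and the pole
#'   approached at onset in `autocorr_ramp` mode.
#' @param dropout_rate expected missing blocks per day.
#' @param dropout_block_s block length in seconds.
#' @param drift_timescale_days timescale of the log-amplitude random
#'   walk (per-day step SD `0.1 / sqrt(drift_timescale_days)`).
#' @param seed integer; the single source of randomness.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 16, sample_rate = 400,
                       duration_days = 14, seizure_rate = 2,
                       cycle_weights = c(`24` = 0.5, `168` = 0.3),
                       preictal_mode = c("marker", "variance_ramp",
                                         "autocorr_ramp"),
                       preictal_horizon = 15, marker_duration_ms = 25,
                       marker_rate_per_s = 1.0, marker_amplitude = NULL,
                       preictal_scale = 2, ar_pole = 0.95,
                       autocorr_pole_max = 0.995, dropout_rate = 4,
                       dropout_block_s = 30, drift_timescale_days = 30,
                       seed = 1) {
  preictal_mode <- match.arg(preictal_mode)
  stopifnot(n_channels >= 1, sample_rate > 0, duration_days > 0,
            seizure_rate >= 0, ar_pole >= 0, ar_pole < 1,
            autocorr_pole_max > ar_pole, autocorr_pole_max < 1,
            dropout_rate >= 0, dropout_block_s > 0,
            drift_timescale_days > 0,
            marker_rate_per_s >= 0, marker_rate_per_s <= 1)
  if (length(cycle_weights) && (is.null(names(cycle_weights)) ||
      any(cycle_weights < 0 | cycle_weights > 1)))
    stop("cycle_weights must be named (period in hours) with amplitudes in [0,1]")
  if (length(preictal_horizon) == 1) {
    stopifnot(preictal_horizon >= 1)
    preictal_window <- c(1, preictal_horizon + 1)
  } else {
    stopifnot(length(preictal_horizon) == 2,
              preictal_horizon[1] >= 1,
              preictal_horizon[2] > preictal_horizon[1])
    preictal_window <- preictal_horizon
  }
  marker_samples <- max(1L, round(marker_duration_ms / 1000 * sample_rate))
  bg_sd <- sqrt(1 / (1 - ar_pole^2) + 1)   # AR(1) marginal + white noise
  if (is.null(marker_amplitude)) marker_amplitude <- 5 * bg_sd
  structure(list(
    n_channels = as.integer(n_channels), sample_rate = sample_rate,
    duration_days = duration_days, seizure_rate = seizure_rate,
    cycle_weights = cycle_weights, preictal_mode = preictal_mode,
    preictal_window = preictal_window,
    marker_duration_ms = marker_duration_ms,
    marker_samples = marker_samples,
    marker_rate_per_s = marker_rate_per_s,
    marker_amplitude = marker_amplitude,
    preictal_scale = preictal_scale, ar_pole = ar_pole,
    autocorr_pole_max = autocorr_pole_max,
    dropout_rate = dropout_rate, dropout_block_s = dropout_block_s,
    drift_timescale_days = drift_timescale_days,
    background_sd = bg_sd, seed = as.integer(seed)),
    class = "sim_config")
}

#' Desk-scale simulation preset
#'
#' 4 channels at 100 Hz — small enough that a full simulate / train /
#' evaluate cycle runs on one CPU in minutes.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_desk <- function(...) {
  args <- list(n_channels = 4, sample_rate = 100, duration_days = 2,
               seizure_rate = 6, dropout_rate = 2, dropout_block_s = 10)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

n_minutes <- function(config) as.integer(round(config$duration_days * 1440))

#' Draw a seizure schedule from a cycle-modulated Poisson process
#'
#' The per-minute intensity is the base rate modulated multiplicatively
#' by each configured cycle, `rate/1440 * prod_c (1 + a_c cos(2 pi t /
#' P_c))`, so each cycle peaks at its phase origin (e.g. midnight for
#' the 24-h cycle) and the mean onset count stays `rate x duration`.
#' Onsets land at minute resolution. Deterministic for a fixed seed.
#'
#' @param config a `sim_config`.
#' @return a `seizure_catalog` of onset minute indices.
#' @export
generate_seizure_times <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nm <- n_minutes(config)
  if (length(config$cycle_weights)) {
    max_period_min <- max(as.numeric(names(config$cycle_weights))) * 60
    if (nm < max_period_min)
      warning("duration shorter than the longest configured cycle period")
  }
  if (config$seizure_rate == 0) return(seizure_catalog(integer()))
  t_min <- seq_len(nm) - 1
  lambda <- rep(config$seizure_rate / 1440, nm)
  for (k in seq_along(config$cycle_weights)) {
    period_min <- as.numeric(names(config$cycle_weights)[k]) * 60
    lambda <- lambda *
      (1 + config$cycle_weights[[k]] * cos(2 * pi * t_min / period_min))
  }
  set.seed(config$seed)
  onsets <- t_min[stats::runif(nm) < pmin(lambda, 1)]
  seizure_catalog(as.integer(onsets))
}

#' Insert marker pulses into a minute record
#'
#' Superimposes a fixed-shape half-sine pulse of `marker_duration_ms`
#' on every channel at each given sample position. Pure function: the
#' input record is unmodified.
#'
#' @param record a `minute_record`.
#' @param positions 1-based sample indices of pulse starts; each pulse
#'   must fit within the minute.
#' @param config a `sim_config` (supplies pulse length and amplitude).
#' @return a new `minute_record` with pulses added.
#' @export
insert_marker <- function(record, positions, config) {
  stopifnot(inherits(record, "minute_record"), inherits(config, "sim_config"))
  len <- config$marker_samples
  nsamp <- ncol(record$data)
  bad <- positions[positions < 1 | positions + len - 1 > nsamp]
  if (length(bad))
    stop(sprintf("marker position(s) out of range: %s",
                 paste(bad, collapse = ", ")))
  pulse <- config$marker_amplitude * sin(pi * (seq_len(len) - 0.5) / len)
  data <- record$data
  for (p in positions) {
    idx <- p:(p + len - 1)
    data[, idx] <- data[, idx] + rep(pulse, each = nrow(data))
  }
  minute_record(record$start_minute, data, record$sample_rate,
                record$missing_mask)
}

# merged dropout blocks as a two-column matrix of [start, end) sample
# indices on the global sample clock
draw_dropout_blocks <- function(config) {
  total_s <- config$duration_days * 86400
  n_blocks <- stats::rpois(1, config$dropout_rate * config$duration_days)
  if (n_blocks == 0) return(matrix(numeric(), 0, 2))
  starts <- sort(stats::runif(n_blocks, 0, max(0, total_s - config$dropout_block_s)))
  ends <- starts + config$dropout_block_s
  merged <- list(c(starts[1], ends[1]))
  for (i in seq_len(n_blocks)[-1]) {
    last <- merged[[length(merged)]]
    if (starts[i] <= last[2]) {
      merged[[length(merged)]][2] <- max(last[2], ends[i])
    } else {
      merged[[length(merged) + 1]] <- c(starts[i], ends[i])
    }
  }
  do.call(rbind, merged)
}

#' Simulate the continuous recording for a seizure schedule
#'
#' Emits exactly `duration_days * 1440` minute records. Each channel is
#' AR(1)-plus-white background noise with slow amplitude drift; inside
#' the configured pre-ictal window of each onset the chosen signature is
#' applied; dropout blocks mask samples on all channels. The AR state is
#' carried across minute boundaries so the signal is continuous.
#' Deterministic for a fixed config (including seed).
#'
#' @param config a `sim_config`.
#' @param schedule a `seizure_catalog` (onsets within the duration).
#' @param sink optional function called with each `minute_record` as it
#'   is produced (streaming); when `NULL` all records are returned as a
#'   list.
#' @return invisibly `NULL` when `sink` is given, else the list of
#'   `minute_record`s.
#' @export
simulate_recording <- function(config, schedule, sink = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(schedule, "seizure_catalog"))
  nm <- n_minutes(config)
  if (length(schedule$onsets) && max(schedule$onsets) >= nm)
    stop("schedule extends beyond the configured duration")
  rate <- config$sample_rate
  spm <- round(60 * rate)
  nch <- config$n_channels

  set.seed(config$seed + 1L)
  blocks <- draw_dropout_blocks(config)
  drift_step_sd <- 0.1 / sqrt(config$drift_timescale_days)
  log_amp <- rep(0, nch)
  ar_state <- rep(0, nch)
  out <- if (is.null(sink)) vector("list", nm) else NULL

  onsets <- schedule$onsets
  win <- config$preictal_window
  for (m in seq_len(nm) - 1L) {
    if (m > 0 && m %% 1440 == 0)
      log_amp <- log_amp + stats::rnorm(nch, 0, drift_step_sd)
    nxt <- onsets[onsets > m]
    delta <- if (length(nxt)) nxt[1] - m else Inf
    in_window <- delta >= win[1] && delta < win[2]
    progress <- if (in_window) (win[2] - delta) / (win[2] - win[1]) else 0

    pole <- config$ar_pole
    if (in_window && config$preictal_mode == "autocorr_ramp")
      pole <- pole + (config$autocorr_pole_max - pole) * progress

    data <- matrix(0, nch, spm)
    for (ch in seq_len(nch)) {
      ar <- stats::filter(stats::rnorm(spm), pole, method = "recursive",
                          init = ar_state[ch])
      ar_state[ch] <- ar[spm]
      data[ch, ] <- as.numeric(ar) + stats::rnorm(spm)
    }
    amp <- exp(log_amp)
    if (in_window && config$preictal_mode == "variance_ramp")
      amp <- amp * (1 + (config$preictal_scale - 1) * progress)
    data <- data * amp

    rec <- minute_record(m, data, rate)
    if (in_window && config$preictal_mode == "marker") {
      hit <- stats::runif(60) < config$marker_rate_per_s
      if (any(hit)) {
        offs <- floor(stats::runif(sum(hit)) * (spm / 60 - config$marker_samples))
        pos <- (which(hit) - 1) * (spm / 60) + offs + 1
        rec <- insert_marker(rec, as.integer(pos), config)
      }
    }

    if (nrow(blocks)) {
      m_start_s <- m * 60
      for (bi in seq_len(nrow(blocks))) {
        lo <- max(blocks[bi, 1], m_start_s); hi <- min(blocks[bi, 2], m_start_s + 60)
        if (lo < hi) {
          s0 <- floor((lo - m_start_s) * rate) + 1
          s1 <- min(spm, ceiling((hi - m_start_s) * rate))
          rec$missing_mask[, s0:s1] <- TRUE
        }
      }
    }
    if (is.null(sink)) out[[m + 1L]] <- rec else sink(rec)
  }
  if (is.null(sink)) out else invisible(NULL)
}
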