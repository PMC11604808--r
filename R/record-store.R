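#' @useDynLib seizecast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Recording epoch used when none is supplied: a Monday, 1st of January,
# so all calendar cycles (hour/day/week/month) start at zero together.
DEFAULT_EPOCH <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

#' Convert between timestamps and whole minutes since an epoch
#'
#' All labeling, exclusion and splitting logic operates on integer
#' minute indices; calendar semantics (hour of day, day of week, ...)
#' are recovered through the epoch. Intervals are half-open throughout.
#'
#' @param time POSIXct timestamp(s), minute-aligned.
#' @param minute integer minute index(es).
#' @param epoch POSIXct origin of the recording clock.
#' @return `minute_index`: integer minutes since epoch;
#'   `minute_time`: POSIXct.
#' @export
minute_index <- function(time, epoch = DEFAULT_EPOCH) {
  as.integer(round(as.numeric(difftime(time, epoch, units = "mins"))))
}

#' @rdname minute_index
#' @export
minute_time <- function(minute, epoch = DEFAULT_EPOCH) {
  epoch + 60 * as.numeric(minute)
}

#' One minute of raw multi-channel EEG
#'
#' The atomic unit of storage and labeling: a channels x samples matrix
#' of amplitudes with a same-shape logical missing-value mask (TRUE =
#' sample lost, e.g. to a telemetry dropout). Missingness is carried as
#' a mask rather than sentinel floats so the downstream NaN policy is
#' explicit.
#'
#' @param start_minute integer minute index (see [minute_index()]).
#' @param data channels x samples numeric matrix; samples must equal
#'   `round(60 * sample_rate)`.
#' @param sample_rate sampling rate in Hz.
#' @param missing_mask logical matrix of the same shape; default all
#'   FALSE.
#' @return an object of class `minute_record`.
#' @export
minute_record <- function(start_minute, data, sample_rate,
                          missing_mask = NULL) {
  stopifnot(is.matrix(data), sample_rate > 0)
  if (ncol(data) != round(60 * sample_rate))
    stop(sprintf("expected %d samples per channel at %g Hz, got %d",
                 round(60 * sample_rate), sample_rate, ncol(data)))
  if (is.null(missing_mask))
    missing_mask <- matrix(FALSE, nrow(data), ncol(data))
  stopifnot(is.logical(missing_mask), all(dim(missing_mask) == dim(data)))
  structure(
    list(start_minute = as.integer(start_minute), data = data,
         sample_rate = sample_rate, missing_mask = missing_mask),
    class = "minute_record")
}

#' @export
print.minute_record <- function(x, ...) {
  cat(sprintf("minute_record: minute %d, %d ch x %d samples @ %g Hz, %d missing\n",
              x$start_minute, nrow(x$data), ncol(x$data), x$sample_rate,
              sum(x$missing_mask)))
  invisible(x)
}

#' Ordered seizure onset catalog
#'
#' Onset times at minute resolution with per-onset lead flags (a lead
#' seizure has no other seizure in the preceding 4 h; flags are filled
#' by [find_lead_seizures()]).
#'
#' @param onsets strictly increasing integer minute indices.
#' @param lead logical per onset; defaults to NA until computed.
#' @return an object of class `seizure_catalog`.
#' @export
seizure_catalog <- function(onsets, lead = rep(NA, length(onsets))) {
  onsets <- as.integer(onsets)
  if (is.unsorted(onsets, strictly = TRUE))
    stop("onsets must be strictly increasing")
  stopifnot(length(lead) == length(onsets))
  structure(list(onsets = onsets, lead = as.logical(lead)),
            class = "seizure_catalog")
}

#' @export
print.seizure_catalog <- function(x, ...) {
  cat(sprintf("seizure_catalog: %d onsets (%d flagged lead)\n",
              length(x$onsets), sum(x$lead, na.rm = TRUE)))
  invisible(x)
}

#' Read or write a seizure catalog as CSV
#'
#' Columns: `onset_minute` (integer minutes since epoch) and `lead`
#' (logical, may be NA).
#'
#' @param catalog a `seizure_catalog`.
#' @param path CSV path.
#' @export
write_seizure_catalog <- function(catalog, path) {
  utils::write.csv(
    data.frame(onset_minute = catalog$onsets, lead = catalog$lead),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seizure_catalog
#' @export
read_seizure_catalog <- function(path) {
  df <- utils::read.csv(path)
  seizure_catalog(df$onset_minute, df$lead)
}

manifest_path <- function(dir) file.path(dir, "manifest.csv")

#' Write a stream of minute records to an on-disk store
#'
#' Layout: one little-endian binary array file per minute
#' (`minute_<index>.bin`: doubles, channel-major, followed by the
#' missing-sample indices) plus a CSV manifest listing every record.
#' The round-trip through [read_minutes()] is lossless for both data
#' and masks.
#'
#' @param records list of `minute_record`, sorted by start minute, or a
#'   function `(emit)` that calls `emit(record)` for each minute
#'   (streaming write, so months of signal never sit in memory).
#' @param dir store directory (created if needed).
#' @param patient_id label recorded in the manifest.
#' @return a `recording_manifest`.
#' @export
write_recording <- function(records, dir, patient_id = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  meta <- list(channels = NA_integer_, sample_rate = NA_real_)
  emit <- function(rec) {
    stopifnot(inherits(rec, "minute_record"))
    key <- as.character(rec$start_minute)
    if (!is.null(seen[[key]]))
      stop(sprintf("duplicate start_time: minute %d", rec$start_minute))
    seen[[key]] <- TRUE
    if (is.na(meta$channels)) {
      meta$channels <<- nrow(rec$data)
      meta$sample_rate <<- rec$sample_rate
    }
    fname <- sprintf("minute_%010d.bin", rec$start_minute)
    con <- file(file.path(dir, fname), "wb")
    on.exit(close(con), add = TRUE)
    miss <- which(rec$missing_mask)
    writeBin(c(nrow(rec$data), ncol(rec$data), length(miss)), con,
             size = 4L, endian = "little")
    writeBin(as.vector(rec$data), con, size = 8L, endian = "little")
    if (length(miss))
      writeBin(as.integer(miss), con, size = 4L, endian = "little")
    rows[[length(rows) + 1L]] <<- data.frame(
      start_minute = rec$start_minute, file = fname)
    invisible(NULL)
  }
  if (is.function(records)) {
    records(emit)
  } else {
    for (rec in records) emit(rec)
  }
  idx <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_minute = integer(), file = character())
  man <- recording_manifest(idx, dir = dir, patient_id = patient_id,
                            channels = meta$channels,
                            sample_rate = meta$sample_rate)
  df <- man$records
  df$patient_id <- rep(man$patient_id, nrow(df))
  df$channels <- rep(man$channels, nrow(df))
  df$sample_rate <- rep(man$sample_rate, nrow(df))
  utils::write.csv(df, manifest_path(dir), row.names = FALSE)
  man
}

#' Index of a stored recording
#'
#' @param records data.frame with columns `start_minute`, `file`.
#' @param dir store directory.
#' @param patient_id,channels,sample_rate recording-level metadata.
#' @return an object of class `recording_manifest`.
#' @export
recording_manifest <- function(records, dir, patient_id = "synthetic",
                               channels = NA_integer_,
                               sample_rate = NA_real_) {
  if (nrow(records) && is.unsorted(records$start_minute, strictly = TRUE))
    stop("manifest start times must be strictly increasing")
  structure(list(records = records, dir = dir, patient_id = patient_id,
                 channels = channels, sample_rate = sample_rate),
            class = "recording_manifest")
}

#' @export
print.recording_manifest <- function(x, ...) {
  cat(sprintf("recording_manifest: patient %s, %d minutes, %s ch @ %s Hz\n  dir: %s\n",
              x$patient_id, nrow(x$records), x$channels, x$sample_rate, x$dir))
  invisible(x)
}

#' @rdname write_recording
#' @param path directory previously written by `write_recording`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(manifest_path(path))
  recording_manifest(df[, c("start_minute", "file")], dir = path,
                     patient_id = if (nrow(df)) df$patient_id[1] else "unknown",
                     channels = if (nrow(df)) df$channels[1] else NA_integer_,
                     sample_rate = if (nrow(df)) df$sample_rate[1] else NA_real_)
}

read_minute_file <- function(path, start_minute, sample_rate) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (length(hdr) != 3L || any(hdr < 0))
    stop(sprintf("corrupted record file: %s", path))
  nch <- hdr[1]; nsamp <- hdr[2]; nmiss <- hdr[3]
  dat <- readBin(con, "double", nch * nsamp, size = 8L, endian = "little")
  if (length(dat) != nch * nsamp)
    stop(sprintf("corrupted record file: %s", path))
  mask <- matrix(FALSE, nch, nsamp)
  if (nmiss > 0) {
    idx <- readBin(con, "integer", nmiss, size = 4L, endian = "little")
    if (length(idx) != nmiss) stop(sprintf("corrupted record file: %s", path))
    mask[idx] <- TRUE
  }
  minute_record(start_minute, matrix(dat, nch, nsamp), sample_rate, mask)
}

#' Read minute records in a half-open time range
#'
#' Returns records with `start_minute` in `[from, to)`, in order.
#' Minutes absent from the store are skipped silently but reported.
#'
#' @param manifest a `recording_manifest`.
#' @param from,to integer minute indices, half-open range.
#' @return list with `records` (list of `minute_record`) and `gaps`
#'   (integer vector of missing minute indices in the range).
#' @export
read_minutes <- function(manifest, from, to) {
  sel <- manifest$records$start_minute >= from &
    manifest$records$start_minute < to
  rows <- manifest$records[sel, , drop = FALSE]
  recs <- lapply(seq_len(nrow(rows)), function(i)
    read_minute_file(file.path(manifest$dir, rows$file[i]),
                     rows$start_minute[i], manifest$sample_rate))
  gaps <- setdiff(seq(from, length.out = max(0, to - from)),
                  rows$start_minute)
  list(records = recs, gaps = as.integer(gaps))
}
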