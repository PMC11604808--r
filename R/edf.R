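# EDF+ writer for stored recordings. Fields are fixed-width ASCII per
# the EDF specification; signals are scaled to 16-bit integers with a
# per-channel symmetric physical range; one data record = 1 s. An
# "EDF Annotations" signal carries the per-record timekeeping TALs and
# a "dropout" annotation at the start of each missing block.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  sprintf(sprintf("%%-%ds", width), s)
}

#' Export a time range of a recording as an EDF+ file
#'
#' Concatenates the stored minutes in `[from, to)` into one continuous
#' EDF+ file with 1-s data records. Missing samples (and whole missing
#' minutes) are written as zeros and flagged as `dropout` annotations
#' in the annotation channel.
#'
#' @param manifest a `recording_manifest`.
#' @param from,to half-open minute range to export.
#' @param path output `.edf` path.
#' @param epoch calendar origin used for the EDF start date/time.
#' @return invisibly, a list with `n_records` (seconds written) and
#'   `samples_per_channel`.
#' @export
export_edf <- function(manifest, from, to, path, epoch = DEFAULT_EPOCH) {
  stopifnot(inherits(manifest, "recording_manifest"), to > from)
  rate <- manifest$sample_rate
  if (is.na(rate) || rate != round(rate))
    stop("EDF export requires a single integer sample rate")
  got <- read_minutes(manifest, from, to)
  if (length(got$records) == 0) stop("empty range: nothing to export")
  nch <- manifest$channels
  n_min <- to - from
  spm <- round(60 * rate)

  sig <- matrix(0, nch, n_min * spm)
  miss <- matrix(FALSE, nch, n_min * spm)
  present <- logical(n_min)
  for (r in got$records) {
    k <- r$start_minute - from
    idx <- (k * spm + 1):((k + 1) * spm)
    sig[, idx] <- r$data
    miss[, idx] <- r$missing_mask
    present[k + 1] <- TRUE
  }
  for (k in which(!present))
    miss[, ((k - 1) * spm + 1):(k * spm)] <- TRUE
  sig[miss] <- 0

  phys_max <- ceiling(apply(abs(sig), 1, max))   # integer-valued: the
  phys_max[phys_max == 0] <- 1                   # field is 8 ASCII chars
  dig <- round(sweep(sig, 1, phys_max, `/`) * 32767)

  n_rec <- n_min * 60
  ann_bytes <- 60L                                  # 30 2-byte samples
  start <- minute_time(from, epoch)
  ns <- nch + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(sprintf("X X X %s", manifest$patient_id), 80),
    edf_field(sprintf("Startdate %s X X X",
                      toupper(format(start, "%d-%b-%Y"))), 80),
    format(start, "%d.%m.%y"), format(start, "%H.%M.%S"),
    edf_field(256 * (ns + 1), 8),
    edf_field("EDF+C", 44),
    edf_field(n_rec, 8),
    edf_field("1", 8),
    edf_field(ns, 4))
  labels <- c(sprintf("EEG ch%d", seq_len(nch)), "EDF Annotations")
  sig_hdr <- paste0(
    paste0(vapply(labels, edf_field, "", width = 16), collapse = ""),
    strrep(edf_field("", 80), ns),                  # transducer
    paste0(c(rep(edf_field("uV", 8), nch), edf_field("", 8)), collapse = ""),
    paste0(c(vapply(-phys_max, edf_field, "", width = 8),
             edf_field(-1, 8)), collapse = ""),
    paste0(c(vapply(phys_max, edf_field, "", width = 8),
             edf_field(1, 8)), collapse = ""),
    strrep(edf_field(-32768, 8), ns),
    strrep(edf_field(32767, 8), ns),
    strrep(edf_field("", 80), ns),                  # prefiltering
    paste0(c(rep(edf_field(rate, 8), nch),
             edf_field(ann_bytes / 2, 8)), collapse = ""),
    strrep(edf_field("", 32), ns))
  writeBin(charToRaw(paste0(hdr, sig_hdr)), con)

  # dropout blocks (merged across channels) on the second clock
  any_miss <- apply(miss, 2, any)
  rl <- rle(any_miss)
  ends <- cumsum(rl$lengths)
  starts_idx <- ends - rl$lengths + 1
  blocks <- cbind((starts_idx[rl$values] - 1) / rate,
                  ends[rl$values] / rate)

  for (rec in seq_len(n_rec) - 1L) {
    for (ch in seq_len(nch)) {
      idx <- (rec * rate + 1):((rec + 1) * rate)
      writeBin(as.integer(dig[ch, idx]), con, size = 2L, endian = "little")
    }
    tal <- sprintf("+%d\x14\x14", rec)
    if (nrow(blocks)) {
      here <- blocks[, 1] >= rec & blocks[, 1] < rec + 1
      for (bi in which(here)) {
        extra <- sprintf("+%g\x15%g\x14dropout\x14", blocks[bi, 1],
                         blocks[bi, 2] - blocks[bi, 1])
        if (nchar(tal) + nchar(extra) < ann_bytes) tal <- paste0(tal, extra)
      }
    }
    ann <- charToRaw(tal)
    writeBin(c(ann, raw(ann_bytes - length(ann))), con)
  }
  invisible(list(n_records = n_rec, samples_per_channel = n_rec * rate))
}
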