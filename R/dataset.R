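#' Labeling paradigm: time-before-seizure bins
#'
#' A paradigm is an ordered list of contiguous half-open bins
#' `[lower, upper)` in minutes before the next lead seizure; labels are
#' `0:(n_labels-1)` with label 0 the closest-to-seizure bin. Minutes
#' whose distance falls below the first lower bound are excluded (the
#' seizure-prediction-horizon gap).
#'
#' @param name paradigm name.
#' @param lower,upper numeric vectors of bin bounds in minutes;
#'   contiguous (`upper[i] == lower[i+1]`), final upper bound `Inf`.
#' @return an object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(name, lower, upper) {
  stopifnot(length(lower) == length(upper), length(lower) >= 2,
            all(upper > lower), is.infinite(upper[length(upper)]))
  if (any(upper[-length(upper)] != lower[-1]))
    stop("bins must be contiguous")
  structure(list(name = name, lower = lower, upper = upper,
                 n_labels = length(lower)),
            class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf("paradigm '%s': %d labels\n", x$name, x$n_labels))
  for (i in seq_len(x$n_labels))
    cat(sprintf("  label %d: [%g, %g) min before lead seizure\n",
                i - 1, x$lower[i], x$upper[i]))
  invisible(x)
}

#' Named paradigm presets
#'
#' `paradigm1`: pre-ictal 1-16 min / inter-ictal beyond;
#' `paradigm2`: 1-4 min / beyond;
#' `paradigm3`: four labels at 1-15 / 15-75 / 75 min-24 h / > 24 h;
#' `paradigm4`: five labels at 1-5 / 5-65 / 65 min-8 h / 8-24 h / > 24 h;
#' `dlstm_40_80`: pre-ictal 40-80 min / inter-ictal > 80 min (the
#' classifier-retargeting labels; minutes closer than 40 min are
#' excluded).
#'
#' @param name one of the preset names.
#' @return a `paradigm_spec`.
#' @export
paradigm_preset <- function(name) {
  switch(name,
    paradigm1 = paradigm_spec("paradigm1", c(1, 16), c(16, Inf)),
    paradigm2 = paradigm_spec("paradigm2", c(1, 4), c(4, Inf)),
    paradigm3 = paradigm_spec("paradigm3", c(1, 15, 75, 1440),
                              c(15, 75, 1440, Inf)),
    paradigm4 = paradigm_spec("paradigm4", c(1, 5, 65, 480, 1440),
                              c(5, 65, 480, 1440, Inf)),
    dlstm_40_80 = paradigm_spec("dlstm_40_80", c(40, 80), c(80, Inf)),
    stop(sprintf("unknown paradigm preset '%s'", name)))
}

#' Flag lead seizures
#'
#' A lead seizure has no other seizure in the open interval of `gap`
#' minutes before it (an onset exactly `gap` minutes earlier still
#' counts as lead); the first seizure is always lead.
#'
#' @param catalog a `seizure_catalog`.
#' @param gap_minutes lead gap, default 240 (4 h).
#' @return the catalog with `lead` flags filled.
#' @export
find_lead_seizures <- function(catalog, gap_minutes = 240) {
  stopifnot(inherits(catalog, "seizure_catalog"))
  on <- catalog$onsets
  lead <- vapply(seq_along(on), function(i) {
    !any(on > on[i] - gap_minutes & on < on[i])
  }, logical(1))
  seizure_catalog(on, lead)
}

next_lead_delta <- function(minutes, catalog) {
  leads <- catalog$onsets[which(catalog$lead)]
  if (length(leads) == 0) return(rep(NA_real_, length(minutes)))
  idx <- findInterval(minutes, leads) + 1L   # first lead strictly > minute
  ifelse(idx <= length(leads), leads[idx] - minutes, NA_real_)
}

#' Eligible minutes after the standard exclusions
#'
#' Removes minutes in the first `exclusion_days` days of the recording,
#' minutes within `postictal_minutes` after any seizure (including the
#' onset minute itself), and — under the default tail policy — minutes
#' after the last lead seizure, whose true distance-to-seizure is
#' unknowable. Candidates should already have passed [screen_minute()].
#'
#' @param minutes integer vector of candidate minute indices.
#' @param catalog a `seizure_catalog` with lead flags.
#' @param exclusion_days days dropped from the start (default 100;
#'   configurable for desk-scale runs).
#' @param postictal_minutes post-ictal exclusion (default 240 = 4 h).
#' @param include_tail keep minutes after the last lead seizure and
#'   label them by the open-ended bin (default FALSE).
#' @return sorted integer vector of eligible minutes.
#' @export
apply_exclusions <- function(minutes, catalog, exclusion_days = 100,
                             postictal_minutes = 240,
                             include_tail = FALSE) {
  stopifnot(inherits(catalog, "seizure_catalog"))
  if (anyNA(catalog$lead)) stop("run find_lead_seizures() first")
  keep <- minutes >= exclusion_days * 1440
  for (o in catalog$onsets)
    keep <- keep & !(minutes >= o & minutes < o + postictal_minutes)
  if (!include_tail) {
    delta <- next_lead_delta(minutes, catalog)
    keep <- keep & !is.na(delta)
  }
  sort(minutes[keep])
}

#' Label minutes by time to the next lead seizure
#'
#' `delta` = next lead-seizure onset minus minute start, in minutes;
#' the label is the paradigm bin containing `delta` (bins half-open
#' `[lower, upper)`). Returns `NA` for sub-horizon minutes
#' (`delta < lower[1]`) and, unless the tail policy allows, for minutes
#' after the last lead seizure.
#'
#' @param minutes integer vector of minute indices.
#' @param catalog a `seizure_catalog` with lead flags.
#' @param paradigm a `paradigm_spec`.
#' @param include_tail label post-final-seizure minutes with the
#'   open-ended bin instead of excluding them.
#' @return integer vector of labels (`NA` = excluded).
#' @export
label_minutes <- function(minutes, catalog, paradigm, include_tail = FALSE) {
  stopifnot(inherits(paradigm, "paradigm_spec"))
  delta <- next_lead_delta(minutes, catalog)
  lab <- rep(NA_integer_, length(minutes))
  for (i in seq_len(paradigm$n_labels)) {
    hit <- !is.na(delta) & delta >= paradigm$lower[i] & delta < paradigm$upper[i]
    lab[hit] <- i - 1L
  }
  if (include_tail)
    lab[is.na(delta)] <- paradigm$n_labels - 1L
  lab
}

#' Seizure-based 80:20 train/test split
#'
#' The first `floor(train_fraction * n_lead)` lead seizures go to
#' training; the boundary is the midpoint between the last training
#' lead and the first test lead, so no time-correlated minute can sit
#' on both sides.
#'
#' @param catalog a `seizure_catalog` with lead flags (>= 2 leads).
#' @param train_fraction fraction of lead seizures for training.
#' @return an object of class `split_spec` with `boundary_minute`,
#'   `n_train_leads`, `n_test_leads`.
#' @export
split_by_seizures <- function(catalog, train_fraction = 0.8) {
  stopifnot(inherits(catalog, "seizure_catalog"))
  if (anyNA(catalog$lead)) stop("run find_lead_seizures() first")
  leads <- catalog$onsets[which(catalog$lead)]
  if (length(leads) < 2) stop("need at least 2 lead seizures to split")
  k <- floor(train_fraction * length(leads))
  k <- min(max(k, 1L), length(leads) - 1L)
  boundary <- floor((leads[k] + leads[k + 1]) / 2)
  structure(list(boundary_minute = as.integer(boundary),
                 n_train_leads = as.integer(k),
                 n_test_leads = as.integer(length(leads) - k)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split: boundary minute %d (%d train / %d test lead seizures)\n",
              x$boundary_minute, x$n_train_leads, x$n_test_leads))
  invisible(x)
}

#' Up-sampling tier start offsets
#'
#' Tier 1: even non-overlapping starts (0, d, 2d, ...); tier 2: the
#' same grid shifted by d/2; tier 3: shifted by d/4; tier 4 draws
#' random starts on a 2.5-ms grid in `[0, 60 - d]`.
#'
#' @param duration segment duration in seconds.
#' @param tier 1, 2 or 3.
#' @return numeric vector of start offsets in seconds.
#' @export
tier_starts <- function(duration, tier) {
  off <- c(0, duration / 2, duration / 4)[tier]
  seq(off, 60 - duration, by = duration)
}

random_tier_start <- function(duration) {
  grid <- 0.0025
  floor(stats::runif(1) * ((60 - duration) / grid + 1)) * grid
}

#' Balanced LSTM training set through tiered up-sampling
#'
#' The majority label contributes the first segment of each of its
#' minutes; minority labels are up-sampled per minute through
#' progressively overlapping tiers — even starts, then offsets of d/2
#' and d/4, and finally random starts on a 2.5-ms grid — until every
#' label matches the majority count. Draws within a tier are spread
#' round-robin across that label's minutes so no single minute
#' dominates.
#'
#' @param labeled data.frame with columns `minute`, `label` (eligible,
#'   labeled minutes; no NA labels).
#' @param fetch_minute function(minute) returning the normalized
#'   `minute_record`.
#' @param duration segment duration in seconds.
#' @param seed integer seed for the random tier.
#' @return list with `items` (data.frame minute/start_offset/tier/label)
#'   and `x` (array `n x channels x samples`), `labels`.
#' @export
build_lstm_train_set <- function(labeled, fetch_minute, duration = 10,
                                 seed = 1) {
  stopifnot(all(c("minute", "label") %in% names(labeled)),
            !anyNA(labeled$label))
  if (nrow(labeled) == 0) stop("no labeled minutes to build from")
  counts <- table(labeled$label)
  all_labels <- sort(unique(labeled$label))
  target <- max(counts)
  set.seed(seed)
  rows <- list()
  for (lab in all_labels) {
    mins <- labeled$minute[labeled$label == lab]
    if (length(mins) == 0) stop(sprintf("label %s has zero minutes", lab))
    got <- 0L
    for (tier in 1:3) {
      starts <- tier_starts(duration, tier)
      for (s in starts) {
        for (m in mins) {
          if (got >= target) break
          rows[[length(rows) + 1]] <- data.frame(
            minute = m, start_offset = s, tier = tier, label = lab)
          got <- got + 1L
        }
        if (got >= target) break
      }
      if (got >= target) break
    }
    mi <- 1L
    while (got < target) {                 # tier 4: random top-up
      rows[[length(rows) + 1]] <- data.frame(
        minute = mins[mi], start_offset = random_tier_start(duration),
        tier = 4L, label = lab)
      got <- got + 1L
      mi <- if (mi == length(mins)) 1L else mi + 1L
    }
  }
  items <- do.call(rbind, rows)
  extract_item_segments(items, fetch_minute, duration)
}

# shared extraction: items -> (B, C, T) array
extract_item_segments <- function(items, fetch_minute, duration) {
  cache_minute <- NULL; cache_rec <- NULL
  items <- items[order(items$minute), ]
  x <- NULL
  for (i in seq_len(nrow(items))) {
    m <- items$minute[i]
    if (is.null(cache_minute) || m != cache_minute) {
      cache_rec <- fetch_minute(m)
      cache_minute <- m
    }
    seg <- extract_segments(cache_rec, items$start_offset[i], duration)[[1]]
    if (is.null(x))
      x <- array(0, c(nrow(items), nrow(seg$data), ncol(seg$data)))
    x[i, , ] <- seg$data
  }
  list(items = items, x = x, labels = items$label)
}

#' Unbalanced test set: five segments per minute
#'
#' Every eligible test minute contributes exactly the five
#' non-overlapping segments of the test convention
#' ([test_segment_starts()]); label proportions are left untouched.
#'
#' @inheritParams build_lstm_train_set
#' @return list as in [build_lstm_train_set()].
#' @export
build_test_set <- function(labeled, fetch_minute, duration = 10) {
  stopifnot(!anyNA(labeled$label))
  starts <- test_segment_starts(duration)
  items <- do.call(rbind, lapply(seq_len(nrow(labeled)), function(i)
    data.frame(minute = labeled$minute[i], start_offset = starts,
               tier = 0L, label = labeled$label[i])))
  extract_item_segments(items, fetch_minute, duration)
}

#' Balanced classifier training set via multiplicative jitter
#'
#' Minute-level classifier inputs for minority labels are duplicated,
#' each duplicated value multiplied by an independent uniform factor in
#' `[0.95, 1.05]` (so zeros stay zero), until all per-label counts
#' match the majority.
#'
#' @param x numeric matrix of classifier inputs (rows = minutes).
#' @param labels integer labels per row.
#' @param seed integer seed.
#' @return list with balanced `x` and `labels`.
#' @export
build_classifier_train_set <- function(x, labels, seed = 1) {
  stopifnot(nrow(x) == length(labels))
  set.seed(seed)
  counts <- table(labels)
  target <- max(counts)
  add_x <- list(); add_y <- list()
  for (lab in as.integer(names(counts))) {
    idx <- which(labels == lab)
    need <- target - length(idx)
    if (need <= 0) next
    src <- idx[((seq_len(need) - 1L) %% length(idx)) + 1L]
    noise <- matrix(stats::runif(need * ncol(x), 0.95, 1.05), need, ncol(x))
    add_x[[length(add_x) + 1]] <- x[src, , drop = FALSE] * noise
    add_y[[length(add_y) + 1]] <- rep(lab, need)
  }
  list(x = do.call(rbind, c(list(x), add_x)),
       labels = c(labels, unlist(add_y)))
}
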