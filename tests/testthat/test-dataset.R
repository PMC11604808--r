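test_that("lead-seizure flags follow the 4-h open-interval rule", {
  expect_equal(find_lead_seizures(seizure_catalog(100L))$lead, TRUE)
  # onsets at 0 h, 3 h, 10 h: leads are 0 h and 10 h
  cat1 <- find_lead_seizures(seizure_catalog(c(0L, 180L, 600L)))
  expect_equal(cat1$lead, c(TRUE, FALSE, TRUE))
  # exactly 4 h apart: the open interval leaves them all lead
  cat2 <- find_lead_seizures(seizure_catalog(c(0L, 240L, 480L)))
  expect_true(all(cat2$lead))
  cat3 <- find_lead_seizures(seizure_catalog(c(0L, 239L)))
  expect_equal(cat3$lead, c(TRUE, FALSE))
})

test_that("exclusions match brute-force enumeration on a toy catalog", {
  # 10-h recording, seizures at 5 h and 5.5 h (second non-lead)
  onsets <- c(300L, 330L)
  catalog <- find_lead_seizures(seizure_catalog(onsets))
  minutes <- 0:599
  got <- apply_exclusions(minutes, catalog, exclusion_days = 0,
                          postictal_minutes = 240)
  # independent enumeration of the rules
  leads <- onsets[catalog$lead]
  oracle <- Filter(function(m) {
    if (any(m >= onsets & m < onsets + 240)) return(FALSE)
    nxt <- leads[leads > m]
    length(nxt) > 0                        # tail excluded by default
  }, minutes)
  expect_equal(got, as.integer(oracle))
  expect_equal(got, 0:299)
  # the 100-day initial exclusion
  catalog2 <- find_lead_seizures(seizure_catalog(101L * 1440L))
  m2 <- seq(99L * 1440L, 101L * 1440L)
  got2 <- apply_exclusions(m2, catalog2, exclusion_days = 100)
  expect_true(all(got2 >= 100 * 1440))
  # no seizures, zero exclusion days, tail allowed: everything kept
  none <- find_lead_seizures(seizure_catalog(integer()))
  expect_equal(apply_exclusions(0:49, none, exclusion_days = 0,
                                include_tail = TRUE), 0:49)
})

test_that("labelers produce the advertised bins over an exhaustive sweep", {
  onset <- 5000L
  catalog <- find_lead_seizures(seizure_catalog(onset))
  sweep_delta <- 1:2880                     # 1 min .. 48 h
  minutes <- onset - sweep_delta
  for (preset in c("paradigm1", "paradigm2", "paradigm3", "paradigm4")) {
    p <- paradigm_preset(preset)
    lab <- label_minutes(minutes, catalog, p)
    expect_false(anyNA(lab))
    expect_equal(sort(unique(lab)), 0:(p$n_labels - 1))
    # contiguous runs in delta order: labels only step upward
    expect_true(all(diff(lab) >= 0))
  }
  p3 <- paradigm_preset("paradigm3")
  expect_equal(label_minutes(onset - 30L, catalog, p3), 1L)  # 15-75 min bin
  p1 <- paradigm_preset("paradigm1")
  expect_equal(label_minutes(onset - 10L, catalog, p1), 0L)  # pre-ictal
  p4 <- paradigm_preset("paradigm4")
  expect_equal(label_minutes(onset - 25L * 60L, catalog, p4), 4L) # > 24 h
  # dLSTM labels: 40-80 pre-ictal, beyond 80 inter-ictal, below 40 excluded
  dl <- paradigm_preset("dlstm_40_80")
  expect_equal(label_minutes(onset - c(39L, 40L, 79L, 80L, 500L), catalog, dl),
               c(NA, 0L, 0L, 1L, 1L))
  # minutes after the final seizure: excluded unless the tail policy allows
  expect_true(is.na(label_minutes(onset + 10L, catalog, p1)))
  expect_equal(label_minutes(onset + 10L, catalog, p1, include_tail = TRUE),
               1L)
})

test_that("the seizure-based split takes floor(80%) and the midpoint", {
  leads <- as.integer(seq(1000, by = 5000, length.out = 10))
  catalog <- find_lead_seizures(seizure_catalog(leads))
  sp <- split_by_seizures(catalog, 0.8)
  expect_equal(sp$n_train_leads, 8)
  expect_equal(sp$n_test_leads, 2)
  expect_equal(sp$boundary_minute, (leads[8] + leads[9]) %/% 2)
  # 5 leads -> k = 4
  cat5 <- find_lead_seizures(seizure_catalog(leads[seq(1, 10, 2)]))
  expect_equal(split_by_seizures(cat5, 0.8)$n_train_leads, 4)
  # day-100 / day-110 midpoint lands on day 105
  catd <- find_lead_seizures(seizure_catalog(c(100L, 110L) * 1440L))
  expect_equal(split_by_seizures(catd, 0.5)$boundary_minute, 105L * 1440L)
  expect_error(split_by_seizures(find_lead_seizures(seizure_catalog(5L))),
               "at least 2")
})

make_fetch <- function(n_channels = 1, sample_rate = 10) {
  function(m) make_minute(m, n_channels, sample_rate, seed = m)
}

test_that("tiered up-sampling balances labels and fills tiers in order", {
  # 1 pre-ictal minute vs 6 inter-ictal minutes, 10-s segments:
  # the pre-ictal minute yields its 6 even starts (tier 1 exhausted)
  labeled <- data.frame(minute = c(10L, 20:25), label = c(0L, rep(1L, 6)))
  ts <- build_lstm_train_set(labeled, make_fetch(), duration = 10, seed = 1)
  expect_equal(as.integer(table(ts$labels)), c(6L, 6L))
  pre <- ts$items[ts$items$label == 0, ]
  expect_equal(sort(pre$start_offset), c(0, 10, 20, 30, 40, 50))
  expect_true(all(pre$tier == 1))
  inter <- ts$items[ts$items$label == 1, ]
  expect_true(all(inter$start_offset == 0))    # first 10 s of each file
  # equally represented labels need no up-sampling at all
  eq <- data.frame(minute = 0:5, label = rep(0:1, 3))
  ts2 <- build_lstm_train_set(eq, make_fetch(), duration = 10, seed = 1)
  expect_true(all(ts2$items$tier == 1))
  expect_true(all(ts2$items$start_offset == 0))
  expect_error(
    build_lstm_train_set(data.frame(minute = 1L, label = 2L)[0, ],
                         make_fetch()))
})

test_that("tier offsets and the random 2.5-ms grid are honored", {
  expect_equal(tier_starts(10, 1), c(0, 10, 20, 30, 40, 50))
  expect_equal(tier_starts(10, 2), c(5, 15, 25, 35, 45))
  expect_equal(tier_starts(10, 3), c(2.5, 12.5, 22.5, 32.5, 42.5))
  # one minority minute vs 20 majority minutes forces the random tier
  # (tiers 1-3 provide 6 + 5 + 5 = 16 segments)
  labeled <- data.frame(minute = c(1L, 100:119),
                        label = c(0L, rep(1L, 20)))
  ts <- build_lstm_train_set(labeled, make_fetch(), duration = 10, seed = 2)
  expect_equal(as.integer(table(ts$labels)), c(20L, 20L))
  r4 <- ts$items[ts$items$tier == 4, ]
  expect_equal(nrow(r4), 4)
  expect_true(all(abs(round(r4$start_offset / 0.0025) -
                        r4$start_offset / 0.0025) < 1e-9))
  expect_true(all(r4$start_offset >= 0 & r4$start_offset <= 50))
  # segment data equal the source samples exactly
  one <- ts$items[1, ]
  rec <- make_fetch()(one$minute)
  i0 <- round(one$start_offset * 10) + 1
  expect_equal(ts$x[1, 1, ], rec$data[1, i0:(i0 + 99)])
})

test_that("the test set keeps natural proportions, five segments a minute", {
  labeled <- data.frame(minute = 0:99,
                        label = rep(c(0L, 1L), c(20, 80)))
  ts <- build_test_set(labeled, make_fetch(), duration = 10)
  expect_equal(nrow(ts$items), 500)
  expect_equal(as.integer(table(ts$labels)) / 500, c(0.2, 0.8))
  expect_true(all(ts$items$start_offset %in% c(0, 10, 20, 30, 40)))
  # no segment crosses a minute boundary
  expect_true(all(ts$items$start_offset + 10 <= 60))
})

test_that("classifier up-sampling jitters within 5% and balances", {
  set.seed(1)
  x <- cbind(runif(30, 1, 2), 0)            # second column all zero
  labels <- rep(c(0L, 1L), c(5, 25))
  bal <- build_classifier_train_set(x, labels, seed = 3)
  expect_equal(as.integer(table(bal$labels)), c(25L, 25L))
  expect_true(all(bal$x[, 2] == 0))         # zeros stay zero
  aug <- bal$x[31:50, 1]
  src <- x[rep(1:5, 4), 1]
  ratio <- aug / src
  expect_true(all(ratio >= 0.95 & ratio <= 1.05))
  expect_true(any(ratio != 1))
})

test_that("no training minute crosses the split boundary", {
  set.seed(99)
  onsets <- as.integer(sort(sample(500:20000, 12)))
  catalog <- find_lead_seizures(seizure_catalog(onsets), 120)
  sp <- split_by_seizures(catalog, 0.8)
  eligible <- apply_exclusions(0:20500, catalog, exclusion_days = 0,
                               postictal_minutes = 60)
  train <- eligible[eligible < sp$boundary_minute]
  test <- eligible[eligible >= sp$boundary_minute]
  expect_true(all(train < sp$boundary_minute))
  expect_true(all(test >= sp$boundary_minute))
  expect_equal(length(train) + length(test), length(eligible))
})
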