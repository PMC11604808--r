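test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_channels = 0), "n_channels")
  expect_error(sim_config(cycle_weights = c(`24` = 1.5)), "amplitudes")
  expect_error(sim_config(preictal_horizon = 0.5))
  # marker always spans at least one sample
  cfg <- sim_config(sample_rate = 10, marker_duration_ms = 25)
  expect_gte(cfg$marker_samples, 1)
  expect_equal(sim_config(sample_rate = 400)$marker_samples, 10)  # 25 ms
})

test_that("seizure schedules are deterministic and rate-faithful", {
  cfg <- sim_config(n_channels = 1, sample_rate = 2, duration_days = 5,
                    seizure_rate = 20, cycle_weights = numeric(), seed = 9)
  s1 <- generate_seizure_times(cfg)
  s2 <- generate_seizure_times(cfg)
  expect_identical(s1$onsets, s2$onsets)
  expect_true(all(diff(s1$onsets) > 0))
  expect_true(all(s1$onsets >= 0 & s1$onsets < 5 * 1440))
  # homogeneous limit: mean count = rate x duration (= 100)
  expect_gt(length(s1$onsets), 60)
  expect_lt(length(s1$onsets), 140)
  # zero base rate
  cfg0 <- sim_config(seizure_rate = 0)
  expect_length(generate_seizure_times(cfg0)$onsets, 0)
  expect_warning(
    generate_seizure_times(sim_config(duration_days = 2, seed = 1)),
    "longest configured cycle")
})

test_that("a full-strength circadian cycle concentrates onset hours", {
  cfg <- sim_config(n_channels = 1, sample_rate = 2, duration_days = 40,
                    seizure_rate = 20, cycle_weights = c(`24` = 1),
                    seed = 13)
  on <- generate_seizure_times(cfg)$onsets
  expect_gt(length(on), 500)
  theta <- 2 * pi * (on %% 1440) / 1440
  R <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  z <- length(theta) * R^2
  p_rayleigh <- exp(-z)                 # large-n Rayleigh tail
  expect_lt(p_rayleigh, 1e-3)
  # circular mean sits at the intensity peak (midnight)
  mean_angle <- atan2(mean(sin(theta)), mean(cos(theta)))
  expect_lt(abs(mean_angle), 2 * pi * 2 / 24)   # within 2 h of peak
})

test_that("recordings are deterministic and conserve the minute count", {
  cfg <- sim_config(n_channels = 2, sample_rate = 4,
                    duration_days = 20 / 1440, seizure_rate = 0,
                    cycle_weights = numeric(), dropout_rate = 48, seed = 3)
  sched <- generate_seizure_times(cfg)
  r1 <- simulate_recording(cfg, sched)
  r2 <- simulate_recording(cfg, sched)
  expect_length(r1, 20)
  expect_identical(r1[[7]]$data, r2[[7]]$data)
  expect_identical(r1[[7]]$missing_mask, r2[[7]]$missing_mask)
  # streaming sink sees the identical records
  seen <- list()
  simulate_recording(cfg, sched, sink = function(r)
    seen[[length(seen) + 1]] <<- r)
  expect_length(seen, 20)
  expect_identical(seen[[7]]$data, r1[[7]]$data)
})

test_that("dropout_rate = 0 leaves no missing samples", {
  cfg <- sim_config(n_channels = 2, sample_rate = 4,
                    duration_days = 10 / 1440, dropout_rate = 0,
                    cycle_weights = numeric(), seed = 4)
  recs <- simulate_recording(cfg, seizure_catalog(integer()))
  expect_true(all(vapply(recs, function(r) !any(r$missing_mask), TRUE)))
})

test_that("marker pulses superimpose exactly and only where placed", {
  cfg <- sim_config(n_channels = 3, sample_rate = 400,
                    marker_duration_ms = 25)
  rec <- make_minute(0, 3, 400, seed = 6)
  expect_identical(insert_marker(rec, integer(), cfg)$data, rec$data)
  out <- insert_marker(rec, 1, cfg)
  d <- out$data - rec$data
  expect_true(all(d[, 1:10] != 0))          # 25 ms at 400 Hz = 10 samples
  expect_true(all(d[, 11:24000] == 0))
  expect_equal(max(d), cfg$marker_amplitude, tolerance = 0.05)
  # pure function: input untouched; superposition is additive
  expect_identical(rec$data[1, 1], make_minute(0, 3, 400, seed = 6)$data[1, 1])
  two <- insert_marker(rec, c(1, 1), cfg)
  expect_equal(two$data - rec$data, 2 * d, tolerance = 1e-12)
  expect_error(insert_marker(rec, 23999, cfg), "23999")
})

test_that("the marker signature stays inside the pre-ictal window", {
  cfg <- sim_config(n_channels = 2, sample_rate = 20,
                    duration_days = 40 / 1440, seizure_rate = 0,
                    preictal_mode = "marker", preictal_horizon = 15,
                    marker_amplitude = 1000, dropout_rate = 0,
                    cycle_weights = numeric(), seed = 8)
  sched <- seizure_catalog(30L)
  recs <- simulate_recording(cfg, sched)
  hits <- vapply(recs, function(r) max(abs(r$data)) > 100, TRUE)
  # window is 1..15 min before the onset at minute 30
  expect_true(all(which(hits) - 1 >= 15))
  expect_true(all(which(hits) - 1 <= 29))
  expect_true(any(hits))
})

test_that("the variance ramp reaches the configured factor at onset", {
  n_onsets <- 100
  onsets <- seq(20, by = 13, length.out = n_onsets)
  cfg <- sim_config(n_channels = 2, sample_rate = 20,
                    duration_days = (max(onsets) + 10) / 1440,
                    seizure_rate = 0, preictal_mode = "variance_ramp",
                    preictal_horizon = 5, preictal_scale = 2,
                    dropout_rate = 0, cycle_weights = numeric(),
                    drift_timescale_days = 1e6, seed = 10)
  pre_var <- c(); inter_var <- c()
  simulate_recording(cfg, seizure_catalog(as.integer(onsets)),
                     sink = function(r) {
    delta <- onsets - r$start_minute
    delta <- delta[delta > 0]
    if (length(delta) == 0) return()
    if (min(delta) == 1) pre_var <<- c(pre_var, var(as.vector(r$data)))
    if (min(delta) > 6) inter_var <<- c(inter_var, var(as.vector(r$data)))
  })
  expect_gte(length(pre_var), 100)
  ratio <- mean(pre_var) / mean(inter_var)
  expect_lt(abs(ratio - 4) / 4, 0.2)
})

test_that("the autocorrelation ramp raises the lag-1 autocorrelation", {
  cfg <- sim_config(n_channels = 1, sample_rate = 20,
                    duration_days = 30 / 1440, seizure_rate = 0,
                    preictal_mode = "autocorr_ramp", preictal_horizon = 5,
                    dropout_rate = 0, cycle_weights = numeric(), seed = 12)
  recs <- simulate_recording(cfg, seizure_catalog(25L))
  ac <- vapply(recs, function(r)
    cor(r$data[1, -1], r$data[1, -ncol(r$data)]), 0)
  expect_gt(ac[25], ac[5])                 # minute at onset-1 vs baseline
})
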