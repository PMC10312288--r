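test_that("spike event files parse, group, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("unit_id\ttrial_id\ttime_s",
               "u1\t1\t0.015", "u1\t1\t0.042", "u2\t1\t0.010"), path)
  sts <- read_spike_events(path)
  expect_equal(sts$n_units, 2)
  expect_equal(sts$n_trials, 1)
  expect_equal(sts$spikes[[1]][[1]], c(0.015, 0.042))

  # header-only file -> 0 units
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("unit_id\ttrial_id\ttime_s", empty)
  expect_equal(read_spike_events(empty)$n_units, 0)

  # write(read(f)) is byte-identical for canonically sorted input
  out <- withr::local_tempfile(fileext = ".tsv")
  write_spike_events(sts, out)
  sts2 <- read_spike_events(out)
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_spike_events(sts2, out2)
  expect_identical(readLines(out), readLines(out2))

  # malformed row names the line
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("unit_id\ttrial_id\ttime_s", "u1\t1\toops"), bad)
  expect_error(read_spike_events(bad), "line 1")
})

test_that("trial inclusion rule: correct AND acquisition within 1.5 s", {
  tt <- trial_table(
    trial_id = 1:4, target_direction = c(0, 45, 90, 135),
    t_instruction = rep(0.5, 4), t_go = rep(1.5, 4),
    t_movement_onset = rep(1.75, 4),
    t_acquisition = 1.75 + c(1.2, 1.6, 1.0, 1.4),
    correct = c(TRUE, TRUE, FALSE, TRUE))
  f <- filter_trials(tt)
  expect_equal(f$included, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(f$exclusion_reason[2], "acquisition too slow")
  expect_equal(f$exclusion_reason[3], "incorrect trial")
  # missing event time -> excluded with logged reason, times untouched
  tt$t_movement_onset[1] <- NA
  f2 <- filter_trials(tt)
  expect_false(f2$included[1])
  expect_equal(f2$exclusion_reason[1], "missing event time")
  expect_equal(f2$t_acquisition, tt$t_acquisition)
  expect_lte(sum(f2$included), nrow(tt))
})

test_that("binning is half-open [left, right) with boundary spikes later", {
  expect_equal(bin_spikes(c(0.005, 0.007), 0, 0.010)$matrix[1, ], 1L)
  expect_equal(bin_spikes(numeric(0), 0, 0.200)$matrix[1, ], rep(0L, 20))
  r <- bin_spikes(0.010, 0, 0.020)           # exactly on the bin boundary
  expect_equal(r$matrix[1, ], c(0L, 1L))
  # out-of-window spikes ignored
  expect_equal(sum(bin_spikes(c(-0.5, 0.9), 0, 0.2)$matrix), 0)
})

test_that("binning is idempotent on reconstructed bin-center trains", {
  set.seed(7)
  for (rep in 1:20) {
    spikes <- sort(runif(sample(0:30, 1), 0, 0.5))
    r1 <- bin_spikes(spikes, 0, 0.5)
    r2 <- bin_spikes(raster_to_spikes(r1), 0, 0.5)
    expect_identical(r1$matrix, r2$matrix)
  }
})

test_that("movement onset is 5% of post-Go peak speed", {
  # linear speed ramp 0 -> 0.1 m/s over 1 s after Go => onset at Go + 0.05 s
  t <- seq(0, 2, by = 0.002)
  x <- ifelse(t <= 1, 0, 0.05 * (t - 1)^2)   # speed = 0.1 * (t - 1)
  kin <- kinematics_trace(t, x, numeric(length(t)))
  onset <- detect_movement_onset(kin, t_go = 1, smooth_samples = 1L)
  expect_equal(onset, 1.05, tolerance = 0.01)

  # zero velocity everywhere -> error
  flat <- kinematics_trace(t, rep(0, length(t)), rep(0, length(t)))
  expect_error(detect_movement_onset(flat, t_go = 1), "no movement")

  # minimum-jerk reach: matches an exhaustive scan of the sampled speed trace
  kin2 <- min_jerk_trace(t, t_start = 1.2, duration = 0.4, x1 = 0.08, y1 = 0.06)
  sp <- hand_speed(kin2, smooth_samples = 5L)
  post <- which(t > 1)
  scan_onset <- t[post][which(sp[post] >= 0.05 * max(sp[post]))[1]]
  expect_equal(detect_movement_onset(kin2, t_go = 1), scan_onset)

  # relative threshold => invariant to uniform speed rescaling
  kin3 <- kinematics_trace(t, kin2$x * 3.7, kin2$y * 3.7)
  expect_equal(detect_movement_onset(kin3, t_go = 1),
               detect_movement_onset(kin2, t_go = 1))
})

test_that("trial table and kinematics files round-trip", {
  tt <- filter_trials(trial_table(
    trial_id = 1:2, target_direction = c(0, 180),
    t_instruction = c(0.5, 0.5), t_go = c(1.5, 1.5),
    t_movement_onset = c(1.72, 1.78), t_acquisition = c(2.1, 2.2),
    correct = c(TRUE, TRUE)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tt, path)
  tt2 <- filter_trials(read_trial_table(path))
  expect_equal(tt2$t_go, tt$t_go)
  expect_equal(tt2$included, tt$included)

  kin <- list("1" = min_jerk_trace(seq(0, 1, 0.01), 0.2, 0.4, x1 = 0.08, y1 = 0),
              "2" = min_jerk_trace(seq(0, 1, 0.01), 0.3, 0.4, x1 = 0, y1 = 0.08))
  kp <- withr::local_tempfile(fileext = ".tsv")
  write_kinematics(kin, kp)
  kin2 <- read_kinematics(kp)
  expect_equal(kin2[["2"]]$y, kin[["2"]]$y, tolerance = 1e-12)
})

test_that("functional networks round-trip through text + JSON sidecar", {
  set.seed(11)
  fn <- functional_network(random_fn_matrix(6), unit_ids = paste0("u", 1:6),
                           window = c(0.3, 0.2), trial_id = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fn(fn, path)
  fn2 <- read_fn(path)
  expect_equal(fn2$weights, fn$weights, tolerance = 1e-12)
  expect_equal(fn2$unit_ids, fn$unit_ids)
  expect_equal(fn2$window, fn$window)
})
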