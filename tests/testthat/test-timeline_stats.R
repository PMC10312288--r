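test_that("MWU timeline: identical groups, shifted groups, Bonferroni family", {
  set.seed(301)
  base <- lapply(1:10, function(i) rnorm(30, 0.4, 0.02))
  tl_same <- mwu_timeline(base, base)
  expect_false(any(tl_same$significant))
  expect_true(all(tl_same$p > 0.5))
  expect_equal(unique(tl_same$p_threshold), 0.01 / 10)
  expect_equal(unique(tl_same$family_size), 10)

  shifted <- lapply(base, function(v) v + 0.1)
  tl_shift <- mwu_timeline(base, shifted)
  expect_true(all(tl_shift$significant))

  # corrected significance never occurs without raw significance
  expect_true(all(tl_shift$p[tl_shift$significant] < 0.01))

  # empty group -> untestable window, not significant
  b2 <- base
  b2[[3]] <- numeric(0)
  tl_na <- mwu_timeline(base, b2)
  expect_false(tl_na$testable[3])
  expect_false(tl_na$significant[3])
})

test_that("divergence time requires a sustained run of significance", {
  mk <- function(sig) data.frame(
    time = seq_along(sig) / 100, statistic = 1, p = ifelse(sig, 1e-6, 0.5),
    p_threshold = 1e-3, significant = sig, family_size = length(sig),
    testable = TRUE)
  expect_true(is.na(detect_divergence_time(mk(rep(FALSE, 12)))))
  sig7 <- c(rep(FALSE, 6), rep(TRUE, 6))
  expect_equal(detect_divergence_time(mk(sig7)), 0.07)
  # isolated significant window 4; sustained only from window 9
  iso <- c(rep(FALSE, 3), TRUE, rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(detect_divergence_time(mk(iso)), 0.09)
  # run of two is not sustained
  two <- c(rep(FALSE, 3), TRUE, TRUE, rep(FALSE, 7))
  expect_true(is.na(detect_divergence_time(mk(two))))
})

test_that("GAS timelines on a tuned cohort diverge by target distance", {
  co <- fixture_big_cohort()
  ids <- included_trials(co$trials)
  dirs <- co$trials$target_direction[match(ids, co$trials$trial_id)]
  t_i <- co$trials$t_instruction[1]
  tfns <- build_trial_fns(co$spikes, co$trials, mode = "temporal",
                          align_event = "instruction", window = 0.2,
                          step = 0.1, t_start = t_i - 0.2, t_stop = t_i + 0.6)
  gg <- gas_timeline_groups(tfns, dirs)
  expect_equal(gg$times, seq(0, 0.6, by = 0.1), tolerance = 1e-9)
  tl <- mwu_timeline(gg$groups[["0"]], gg$groups[["180"]], times = gg$times)
  dv <- detect_divergence_time(tl, sustain = 2L)
  # same-direction alignment exceeds opposite-direction post-Instruction
  post <- which(gg$times >= 0.4)
  expect_gt(mean(unlist(gg$groups[["0"]][post])),
            mean(unlist(gg$groups[["180"]][post])))
  expect_false(is.na(dv))
  expect_gte(dv, co$config$tuning_latency)   # nothing diverges before onset
})

test_that("reciprocity baseline test recovers an injected dip", {
  # constructed timeline: rho constant except a dip at 0.2-0.3 s
  set.seed(303)
  times <- seq(0, 0.5, by = 0.05)
  trials <- 1:30
  grid <- expand.grid(trial = trials, time = times)
  dip <- grid$time >= 0.2 & grid$time <= 0.3
  grid$rho <- rnorm(nrow(grid), 0.1, 0.02) - ifelse(dip, 0.15, 0)
  grid$percentile <- 85
  res <- reciprocity_baseline_test(grid)
  expect_length(res$baseline, 30)
  expect_true(res$minimum_time >= 0.2 && res$minimum_time <= 0.3)
  expect_true(res$minimum_significant)
  expect_true(all(res$dip_windows >= 0.2 & res$dip_windows <= 0.3))

  # constant timeline: no significant windows, earliest tie as minimum
  grid2 <- expand.grid(trial = trials, time = times)
  grid2$rho <- 0.1
  grid2$percentile <- 85
  res2 <- reciprocity_baseline_test(grid2)
  expect_false(any(res2$windows$significant))
  expect_equal(res2$minimum_time, times[1])
  expect_false(isTRUE(res2$minimum_significant))

  expect_error(reciprocity_baseline_test(grid, baseline_window = c(9, 10)),
               "baseline")
})

test_that("divergence is a run-level null event under permuted labels", {
  co <- fixture_big_cohort()
  ids <- included_trials(co$trials)
  dirs <- co$trials$target_direction[match(ids, co$trials$trial_id)]
  t_i <- co$trials$t_instruction[1]
  tfns <- build_trial_fns(co$spikes, co$trials, mode = "temporal",
                          align_event = "instruction", window = 0.2,
                          step = 0.1, t_start = t_i - 0.2, t_stop = t_i + 0.6)
  n <- length(tfns)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  times <- tfns[[1]]$times
  gasmat <- vapply(seq_along(times), function(w)
    vapply(seq_len(nrow(pairs)), function(p)
      graph_alignment_score(tfns[[pairs[p, 1]]]$fns[[w]],
                            tfns[[pairs[p, 2]]]$fns[[w]]), numeric(1)),
    numeric(nrow(pairs)))
  run_divergence <- function(dd) {
    delta <- circular_delta(dd[pairs[, 1]], dd[pairs[, 2]])
    g0 <- lapply(seq_along(times), function(w) gasmat[delta == 0, w])
    g180 <- lapply(seq_along(times), function(w) gasmat[delta == 180, w])
    detect_divergence_time(mwu_timeline(g0, g180, times = times),
                           sustain = 2L)
  }
  # true labels: divergence detected (injected correlations are real)
  expect_false(is.na(run_divergence(dirs)))
  # permuted labels: type-I control at the run level
  set.seed(305)
  hits <- vapply(1:40, function(i) !is.na(run_divergence(sample(dirs))),
                 logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("injected reciprocity dip is recovered by the baseline test", {
  co <- fixture_dip_cohort()
  t_i <- co$trials$t_instruction[1]
  tfns <- build_trial_fns(co$spikes, co$trials, mode = "temporal",
                          align_event = "instruction", window = 0.2,
                          step = 0.05, t_start = t_i - 0.2, t_stop = t_i + 0.5)
  nulls <- build_null_fns(co$spikes, co$trials, n_iterations = 10,
                          mode = "temporal", align_event = "instruction",
                          window = 0.2, step = 0.05, t_start = t_i - 0.2,
                          t_stop = t_i + 0.5, seed = 14)
  rt <- reciprocity_timeline(tfns, nulls, percentiles = c(85, 87))
  res <- reciprocity_baseline_test(rt)
  dip <- co$ground_truth$dip_window
  # timestamps are trailing edges, so the window stamped t covers
  # [t - 0.2, t]; "inside the dip" = data interval overlapping the
  # injected dip window by at least half a window (100 ms)
  overlap <- function(t) pmin(t, dip[2]) - pmax(t - 0.2, dip[1])
  in_dip <- overlap(rt$time) >= 0.1
  in_base <- rt$time >= 0 & rt$time <= 0.1
  expect_lt(mean(rt$rho[in_dip], na.rm = TRUE),
            mean(rt$rho[in_base], na.rm = TRUE))
  # detected minimum window overlaps the injected dip window
  expect_gte(overlap(res$minimum_time), 0.1)
})

test_that("reciprocity timeline pipeline wires r, r_bar, rho together", {
  co <- fixture_cohort()
  t_i <- co$trials$t_instruction[1]
  sub <- co$trials[co$trials$trial_id %in% included_trials(co$trials)[1:6], ]
  class(sub) <- class(co$trials)
  spk <- subset_spike_trials(co$spikes, sub$trial_id)
  tfns <- build_trial_fns(spk, sub, mode = "temporal",
                          align_event = "instruction", window = 0.2,
                          step = 0.1, t_start = t_i - 0.2, t_stop = t_i + 0.4)
  nulls <- build_null_fns(spk, sub, n_iterations = 3,
                          mode = "temporal", align_event = "instruction",
                          window = 0.2, step = 0.1, t_start = t_i - 0.2,
                          t_stop = t_i + 0.4, seed = 12)
  rt <- reciprocity_timeline(tfns, nulls, percentiles = c(85, 90))
  expect_s3_class(rt, "reciprocity_timeline")
  expect_setequal(unique(rt$percentile), c(85, 90))
  ok <- !is.na(rt$rho)
  expect_true(any(ok))
  expect_true(all(rt$r[ok] >= 0 & rt$r[ok] <= 1))
  expect_true(all(rt$rho[ok] <= 1 + 1e-12))
  # rho sign matches r vs r_bar
  expect_true(all(sign(rt$rho[ok]) == sign(rt$r[ok] - rt$r_bar[ok]) |
                    rt$rho[ok] == 0))
})
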