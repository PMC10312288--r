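test_that("cohort bookkeeping and instructed-delay schedule", {
  co <- cached_cohort("tiny", cohort_config(n_units = 10L,
                                            n_trials_per_direction = 2L,
                                            seed = 3L))
  expect_equal(co$spikes$n_units, 10)
  expect_equal(nrow(co$trials), 16)
  expect_equal(sum(co$trials$included), 16)
  expect_equal(as.integer(table(co$trials$target_direction)), rep(2L, 8))
  # schedule: Instruction at 0.5 s, Go at 1.5 s (1-s delay), RT in [0.2, 0.3]
  expect_equal(co$trials$t_instruction, rep(0.5, 16))
  expect_equal(co$trials$t_go - co$trials$t_instruction, rep(1.0, 16))
  rt <- co$trials$t_movement_onset - co$trials$t_go
  expect_true(all(rt >= 0.2 & rt <= 0.3))
  expect_equal(co$trials$t_end, co$trials$t_acquisition + 0.5)
  # ground truth references valid units, no self pairs
  for (asm in c(co$ground_truth$pairs, list(co$ground_truth$background))) {
    expect_true(all(asm$src != asm$tgt))
    expect_true(all(c(asm$src, asm$tgt) %in% 1:10))
  }
  # background holds both legs of each reciprocal pair
  bg <- co$ground_truth$background
  expect_true(all(paste(bg$tgt, bg$src) %in% paste(bg$src, bg$tgt)))
  # kinematics end at the instructed target
  k1 <- co$kinematics[["1"]]
  d1 <- co$trials$target_direction[1]
  expect_equal(tail(k1$x, 1), 0.08 * cos(d1 * pi / 180), tolerance = 1e-9)
  expect_equal(tail(k1$y, 1), 0.08 * sin(d1 * pi / 180), tolerance = 1e-9)
})

test_that("same seed reproduces the cohort exactly; config is validated", {
  cfg <- cohort_config(n_units = 6L, n_trials_per_direction = 1L,
                       assembly_size = 8L, seed = 99L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$spikes$spikes, b$spikes$spikes)
  expect_identical(a$trials$t_movement_onset, b$trials$t_movement_onset)
  expect_identical(a$ground_truth, b$ground_truth)

  expect_error(cohort_config(corr_strength = 1.4), "corr_strength")
  expect_error(cohort_config(baseline_rate = 2000), "probability")
  expect_error(generate_cohort(cohort_config(n_units = 4L, assembly_size = 40L)),
               "assembly_size")
})

test_that("corr_strength=0, tuning_depth=0 gives homogeneous Poisson counts", {
  # property over seeds: per-unit counts over >100 trials are unbiased for
  # rate * duration with Poisson dispersion (z within the 3-SE band; the
  # occasional single tail draw is tolerated at its expected frequency)
  z <- unlist(lapply(1:6, function(s) {
    co <- generate_cohort(cohort_config(
      n_units = 8L, n_trials_per_direction = 13L, corr_strength = 0,
      tuning_depth = 0, assembly_size = 8L, baseline_rate = 8, seed = s))
    expected <- 8 * sum(co$trials$t_end)
    vapply(seq_len(8), function(u)
      (sum(lengths(co$spikes$spikes[[u]])) - expected) / sqrt(expected),
      numeric(1))
  }))
  expect_lt(abs(mean(z)), 0.5)           # unbiased (48 draws)
  expect_gte(mean(abs(z) < 3), 0.95)     # Poisson-like dispersion
  expect_lt(max(abs(z)), 4)
})

test_that("injected pairs show excess conditional co-spiking by direct counting", {
  co <- cached_cohort("strongpair", cohort_config(
    n_units = 6L, n_trials_per_direction = 8L, corr_strength = 0.5,
    tuning_depth = 0, assembly_size = 2L, seed = 11L))
  asm <- co$ground_truth$pairs[["0"]]
  a <- asm$src[1]; b <- asm$tgt[1]
  on <- 0.5 + co$ground_truth$injection_onset
  trials0 <- co$trials$trial_id[co$trials$target_direction == 0]
  n_src <- n_co <- n_bins <- n_tgt <- 0
  for (id in trials0) {
    dur <- co$trials$t_end[match(id, co$trials$trial_id)]
    r <- bin_spikes(trial_spikes(co$spikes, id), on, floor((dur - on) / 0.01) * 0.01)
    xa <- r$matrix[a, ]; xb <- r$matrix[b, ]
    Tn <- length(xa) - 1
    n_src <- n_src + sum(xa[1:Tn])
    n_co <- n_co + sum(xa[1:Tn] & (xb[1:Tn] | xb[2:(Tn + 1)]))
    n_tgt <- n_tgt + sum(xb[1:Tn] | xb[2:(Tn + 1)])
    n_bins <- n_bins + Tn
  }
  p_cond <- n_co / n_src          # P(b in bins t..t+1 | a in bin t)
  p_uncond <- n_tgt / n_bins
  expect_gt(p_cond, p_uncond + 0.2)  # corr_strength 0.5 >> chance overlap
})

test_that("cosine fit recovers preferred directions for >= 90% of units", {
  # tuning-only world: injected co-spikes are OFF because they add
  # direction-specific rate to target units and would confound the
  # recovery of the rate-tuning parameter itself
  co <- cached_cohort("tuning_only", cohort_config(
    n_units = 16L, n_trials_per_direction = 10L, corr_strength = 0,
    assembly_size = 8L, seed = 19L))
  dirs8 <- seq(0, 315, by = 45)
  n_units <- co$spikes$n_units
  # per-unit mean post-Instruction rate by direction
  rates <- matrix(0, n_units, 8)
  for (d in seq_along(dirs8)) {
    ids <- co$trials$trial_id[co$trials$target_direction == dirs8[d]]
    tot_t <- 0
    cnt <- numeric(n_units)
    for (id in ids) {
      k <- match(id, co$trials$trial_id)
      lo <- co$trials$t_instruction[k] + co$config$tuning_latency
      hi <- co$trials$t_end[k]
      tot_t <- tot_t + (hi - lo)
      sp <- trial_spikes(co$spikes, id)
      cnt <- cnt + vapply(sp, function(s) sum(s >= lo & s < hi), numeric(1))
    }
    rates[, d] <- cnt / tot_t
  }
  # preferred direction from the circular mean of the tuning curve
  ang <- dirs8 * pi / 180
  est <- atan2(rates %*% sin(ang), rates %*% cos(ang)) * 180 / pi
  est <- (est + 360) %% 360
  err <- circular_delta(est, co$ground_truth$preferred_direction)
  expect_gte(mean(err <= 45), 0.9)
})

test_that("injected pairs carry more conMI than non-injected pairs", {
  co <- fixture_cohort()
  fns <- build_trial_fns(co$spikes, co$trials, mode = "full")
  ids <- included_trials(co$trials)
  dirs <- co$trials$target_direction[match(ids, co$trials$trial_id)]
  inj <- non <- numeric(0)
  for (d in names(co$ground_truth$pairs)) {
    sel <- which(dirs == as.numeric(d))
    asm <- co$ground_truth$pairs[[d]]
    bg <- co$ground_truth$background
    mask <- matrix(FALSE, co$spikes$n_units, co$spikes$n_units)
    mask[cbind(asm$src, asm$tgt)] <- TRUE
    diag(mask) <- NA
    mask[cbind(bg$src, bg$tgt)] <- NA   # background is neither group
    for (s in sel) {
      w <- fns[[s]]$weights
      inj <- c(inj, w[which(mask)])
      non <- c(non, w[which(!mask)])
    }
  }
  expect_gt(mean(inj), mean(non))
})
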