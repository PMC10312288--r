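#' Instantaneous firing rate by Gaussian kernel smoothing
#'
#' Convolves a single-trial spike train with a unit-area Gaussian kernel
#' (default sigma = 20 ms), evaluated on a uniform 1-ms lattice. The profile
#' integrates to the spike count (up to edge truncation) and is the rate
#' signal that drives the rate-matched Poisson surrogates.
#'
#' @param train spike times (s)
#' @param duration trial duration (s); lattice covers `[0, duration)`
#' @param sigma kernel width (s, default 0.020)
#' @param dt lattice step (s, default 0.001)
#' @return object of class `rate_profile`: fields `rate` (Hz, one value per
#'   lattice point), `t` (lattice centers), `sigma`, `dt`
#' @export
instantaneous_rate <- function(train, duration, sigma = 0.020, dt = 0.001) {
  if (sigma <= 0) stop("sigma must be positive")
  t <- seq(dt / 2, duration - dt / 2, by = dt)
  rate <- numeric(length(t))
  half <- ceiling(5 * sigma / dt)   # kernel support truncated at +/- 5 sigma
  for (s in train) {
    center <- round((s - dt / 2) / dt) + 1L
    lo <- max(1L, center - half)
    hi <- min(length(t), center + half)
    rate[lo:hi] <- rate[lo:hi] + stats::dnorm(t[lo:hi], mean = s, sd = sigma)
  }
  structure(list(rate = rate, t = t, sigma = sigma, dt = dt),
            class = "rate_profile")
}

#' Sample a rate-matched surrogate spike train
#'
#' Treats the smoothed rate as the probability of a spike within each 10-ms
#' sampling period of an inhomogeneous Poisson process: per period, a spike
#' is emitted with probability `min(rate * period, 1)` (the cap guards
#' pathological rates) and placed uniformly within the period. The surrogate
#' preserves the unit's single-trial rate profile while jittering precise
#' spike timing within the kernel width.
#'
#' @param profile a [instantaneous_rate()] profile
#' @param sample_period sampling period (s, default 0.010)
#' @param seed optional integer seed for reproducibility
#' @return ascending spike times (s)
#' @export
sample_rate_matched_train <- function(profile, sample_period = 0.010,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  duration <- length(profile$rate) * profile$dt
  starts <- seq(0, duration - sample_period + 1e-12, by = sample_period)
  per <- floor(sample_period / profile$dt + 1e-9)
  # mean rate within each sampling period
  idx <- matrix(seq_len(per * length(starts)), nrow = per)
  p <- pmin(colMeans(matrix(profile$rate[idx], nrow = per)) * sample_period, 1)
  hit <- stats::runif(length(p)) < p
  sort(starts[hit] + stats::runif(sum(hit)) * sample_period)
}

#' Rate-matched surrogate spike train set
#'
#' Regenerates every unit's train on every trial from its own single-trial
#' smoothed rate profile.
#'
#' @param sts a [spike_train_set()]
#' @param trials a [trial_table()] (supplies per-trial durations)
#' @param sigma kernel width (s)
#' @param sample_period Poisson sampling period (s)
#' @param seed master seed; each (unit, trial) gets its own derived substream
#' @return a [spike_train_set()] of surrogate trains
#' @export
surrogate_spike_trains <- function(sts, trials, sigma = 0.020,
                                   sample_period = 0.010, seed = 1L) {
  durations <- trials$t_end[match(sts$trial_ids, trials$trial_id)]
  if (anyNA(durations))
    stop("trial_table lacks trials present in the spike set; ",
         "use subset_spike_trials() first")
  spikes <- lapply(seq_len(sts$n_units), function(u) {
    lapply(seq_len(sts$n_trials), function(k) {
      prof <- instantaneous_rate(sts$spikes[[u]][[k]], durations[k],
                                 sigma = sigma)
      sample_rate_matched_train(prof, sample_period,
                                seed = derive_seed(seed, u, k))
    })
  })
  spike_train_set(spikes, sts$unit_ids, sts$trial_ids)
}

#' Build functional networks from rate-matched surrogates
#'
#' For each iteration, every unit's train on every trial is resampled from
#' its smoothed rate profile and FNs are built with the identical pipeline
#' used on the data. 45 iterations are used to normalize reciprocity; 50
#' were used to illustrate rate preservation.
#'
#' @param sts a [spike_train_set()]
#' @param trials a filtered [trial_table()]
#' @param n_iterations number of independent surrogate draws
#' @param mode `"full"` (one FN per trial) or `"temporal"` (a
#'   [build_temporal_fn()] per trial)
#' @param window,step,bin_width,align_event passed to FN construction for
#'   `mode = "temporal"`; `align_event` is one of `"instruction"`, `"go"`,
#'   `"movement"`, `"start"`.
#' @param t_start,t_stop analyzed extent per trial for temporal mode
#'   (trial clock); defaults to the full trial.
#' @param sigma,sample_period surrogate parameters
#' @param seed master seed; iteration `it` uses substream `(it, unit, trial)`
#' @return list of length `n_iterations`; each element is a list (per
#'   included trial) of [functional_network()] or `temporal_fn` objects
#' @export
build_null_fns <- function(sts, trials, n_iterations = 45L,
                           mode = c("full", "temporal"), window = 0.200,
                           step = 0.010, bin_width = 0.010,
                           align_event = "start", t_start = NULL,
                           t_stop = NULL, sigma = 0.020,
                           sample_period = 0.010, seed = 1L) {
  mode <- match.arg(mode)
  ids <- included_trials(trials)
  lapply(seq_len(n_iterations), function(it) {
    surr <- surrogate_spike_trains(sts, trials, sigma = sigma,
                                   sample_period = sample_period,
                                   seed = derive_seed(seed, it, 0L))
    fns_from_trains(surr, trials, ids, mode, window, step, bin_width,
                    align_event, t_start, t_stop)
  })
}

# shared data/surrogate path: one FN (or temporal FN) per included trial
fns_from_trains <- function(sts, trials, ids, mode, window, step, bin_width,
                            align_event, t_start, t_stop) {
  lapply(ids, function(id) {
    row <- trials[match(id, trials$trial_id), ]
    tr <- trial_spikes(sts, id)
    if (mode == "full") {
      build_full_trial_fn(bin_spikes(tr, 0, row$t_end, bin_width),
                          unit_ids = sts$unit_ids, trial_id = id)
    } else {
      a <- switch(align_event, start = 0, instruction = row$t_instruction,
                  go = row$t_go, movement = row$t_movement_onset,
                  stop("unknown align_event: ", align_event))
      build_temporal_fn(tr,
                        t_start = if (is.null(t_start)) 0 else t_start,
                        t_stop = if (is.null(t_stop)) row$t_end else t_stop,
                        window = window, step = step, bin_width = bin_width,
                        align_time = a, unit_ids = sts$unit_ids,
                        trial_id = id)
    }
  })
}

#' Build data functional networks for all included trials
#'
#' Convenience wrapper applying the FN pipeline trial by trial; the exact
#' same code path used for the surrogates in [build_null_fns()].
#'
#' @inheritParams build_null_fns
#' @return list with one [functional_network()] (mode `"full"`) or
#'   `temporal_fn` (mode `"temporal"`) per included trial
#' @export
build_trial_fns <- function(sts, trials, mode = c("full", "temporal"),
                            window = 0.200, step = 0.010, bin_width = 0.010,
                            align_event = "start", t_start = NULL,
                            t_stop = NULL) {
  mode <- match.arg(mode)
  fns_from_trains(sts, trials, included_trials(trials), mode, window, step,
                  bin_width, align_event, t_start, t_stop)
}

# deterministic substream seed below 2^31 (splitmix-style mix of the parts)
derive_seed <- function(master, a, b = 0L, c = 0L) {
  x <- (as.double(master) * 2654435761 + as.double(a) * 40503 +
        as.double(b) * 2246822519 + as.double(c) * 3266489917) %% 2147483647
  as.integer(x) + 1L
}
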