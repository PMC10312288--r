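#' Synthetic cohort configuration
#'
#' Parameters of the synthetic instructed-delay reaching cohort. The
#' generated world mirrors the recorded task: trial start 0.5 s before the
#' Instruction cue, a 1-s delay, a Go cue, a reaction time of ~0.25 s, a
#' minimum-jerk reach to one of 8 radial targets, and trial end 0.5 s after
#' target acquisition. Units are Poisson with cosine direction tuning that
#' switches on `tuning_latency` after Instruction; direction-specific excess
#' co-spiking at 0-10 ms lags is injected into designated unit pairs; a
#' transient drop in reciprocal co-spiking after Instruction can be injected
#' via `reciprocity_dip`.
#'
#' @param n_units number of units (default 60)
#' @param n_trials_per_direction trials per target (default 30)
#' @param baseline_rate baseline firing rate, Hz (default 8)
#' @param tuning_depth fractional cosine rate modulation (default 0.5)
#' @param tuning_latency s after Instruction at which tuning (and injected
#'   correlation) switches on (default 0.12)
#' @param corr_strength probability that a source spike induces a target
#'   co-spike (default 0.2)
#' @param corr_lag_bins allowed co-spike lags in 10-ms bins (default `c(0, 1)`:
#'   same bin or the next)
#' @param assembly_size directed injected pairs per direction (default 40);
#'   additionally `floor(assembly_size / 2)` direction-blind bidirectional
#'   background pairs carry the network's baseline reciprocity
#' @param reciprocity_dip fraction of bidirectional background pairs whose
#'   reverse-direction injection is silenced inside `dip_window` (default 0)
#' @param dip_window suppression window, s post-Instruction
#'   (default `c(0.15, 0.35)`)
#' @param reaction_time_range uniform reaction-time bounds, s
#' @param move_duration reach duration, s
#' @param reach_radius target distance, m
#' @param kin_rate kinematics sampling rate, Hz
#' @param seed master seed; fixes every draw
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_units = 60L, n_trials_per_direction = 30L,
                          baseline_rate = 8, tuning_depth = 0.5,
                          tuning_latency = 0.12, corr_strength = 0.2,
                          corr_lag_bins = c(0L, 1L), assembly_size = 40L,
                          reciprocity_dip = 0, dip_window = c(0.15, 0.35),
                          reaction_time_range = c(0.2, 0.3),
                          move_duration = 0.4, reach_radius = 0.08,
                          kin_rate = 250, seed = 1L) {
  cfg <- list(n_units = as.integer(n_units),
              n_trials_per_direction = as.integer(n_trials_per_direction),
              baseline_rate = baseline_rate, tuning_depth = tuning_depth,
              tuning_latency = tuning_latency, corr_strength = corr_strength,
              corr_lag_bins = as.integer(corr_lag_bins),
              assembly_size = as.integer(assembly_size),
              reciprocity_dip = reciprocity_dip, dip_window = dip_window,
              reaction_time_range = reaction_time_range,
              move_duration = move_duration, reach_radius = reach_radius,
              kin_rate = kin_rate, seed = as.integer(seed))
  if (cfg$baseline_rate < 0 || cfg$tuning_depth < 0)
    stop("rates and tuning depth must be non-negative")
  if (cfg$corr_strength < 0 || cfg$corr_strength > 1)
    stop("corr_strength must be in [0, 1]")
  peak <- cfg$baseline_rate * (1 + cfg$tuning_depth)
  if (peak * 0.001 > 1)
    stop("config implies per-lattice-step spike probability > 1")
  if (cfg$n_units < 2) stop("need at least 2 units")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic reaching cohort with known ground truth
#'
#' Draws spike trains on a 1-ms Bernoulli lattice thinned to each unit's
#' instantaneous rate (uniformly jittered within the lattice step), builds
#' the trial table and minimum-jerk hand kinematics, injects
#' direction-specific co-spikes into designated source-target pairs, and
#' returns the injected structure as ground truth. Injected co-spikes are
#' *added* to the target train (source trains stay Poisson). Injection and
#' rate tuning are active from `tuning_latency` after the Instruction cue
#' (before that, nothing distinguishes the 8 directions, so pre-Instruction
#' windows are uninformative by construction).
#'
#' @param config a [cohort_config()]
#' @return list with elements `spikes` ([spike_train_set()]), `trials`
#'   (filtered [trial_table()]), `kinematics` (named list of
#'   [kinematics_trace()]), `ground_truth` (preferred directions, injected
#'   pairs per direction with bidirectional/suppressed flags, dip window),
#'   and `config`
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  dirs8 <- seq(0, 315, by = 45)
  n_tr <- config$n_trials_per_direction * 8L
  pref <- dirs8[((seq_len(config$n_units) - 1L) %% 8L) + 1L]

  assemblies <- make_assemblies(config)

  # ---- trial table -------------------------------------------------------
  direction <- sample(rep(dirs8, config$n_trials_per_direction))
  rt <- runif(n_tr, config$reaction_time_range[1], config$reaction_time_range[2])
  t_instr <- rep(0.5, n_tr)
  t_go <- t_instr + 1.0
  t_move <- t_go + rt
  t_acq <- t_move + config$move_duration
  trials <- trial_table(trial_id = seq_len(n_tr), target_direction = direction,
                        t_instruction = t_instr, t_go = t_go,
                        t_movement_onset = t_move, t_acquisition = t_acq,
                        correct = rep(TRUE, n_tr))
  trials <- filter_trials(trials)

  # ---- spikes ------------------------------------------------------------
  lat <- 0.001
  spikes <- rep(list(vector("list", n_tr)), config$n_units)
  for (k in seq_len(n_tr)) {
    dur <- trials$t_end[k]
    n_lat <- floor(dur / lat)
    t_edges <- (seq_len(n_lat) - 1L) * lat
    on <- t_edges >= t_instr[k] + config$tuning_latency
    gain <- 1 + config$tuning_depth *
      cos((direction[k] - pref) * pi / 180)      # per-unit tuned gain
    base <- matrix(config$baseline_rate, nrow = config$n_units, ncol = n_lat)
    base[, on] <- base[, on] * gain
    hit <- matrix(runif(config$n_units * n_lat), nrow = config$n_units) <
      base * lat
    for (u in seq_len(config$n_units)) {
      idx <- which(hit[u, ])
      spikes[[u]][[k]] <- t_edges[idx] + runif(length(idx)) * lat
    }
    if (config$corr_strength > 0) {
      inject <- function(pair_df, t_from) {
        dip_lo <- t_instr[k] + config$dip_window[1]
        dip_hi <- t_instr[k] + config$dip_window[2]
        for (p in seq_len(nrow(pair_df))) {
          src <- spikes[[pair_df$src[p]]][[k]]
          src <- src[src >= t_from]
          if (pair_df$dip_suppressed[p])
            src <- src[src < dip_lo | src > dip_hi]
          if (!length(src)) next
          go <- runif(length(src)) < config$corr_strength
          if (!any(go)) next
          lag_bin <- sample(config$corr_lag_bins, sum(go), replace = TRUE)
          tgt_bin <- floor(src[go] / 0.010) + lag_bin
          t_new <- (tgt_bin + runif(sum(go))) * 0.010
          t_new <- t_new[t_new < dur]
          u_tgt <- pair_df$tgt[p]
          spikes[[u_tgt]][[k]] <<- sort(c(spikes[[u_tgt]][[k]], t_new))
        }
      }
      # direction-blind reciprocal background, active the whole trial
      # (carries the network's baseline reciprocity and the optional dip)
      inject(assemblies$background, t_from = 0)
      # direction-specific assemblies switch on after the Instruction cue
      inject(assemblies$by_direction[[as.character(direction[k])]],
             t_from = t_instr[k] + config$tuning_latency)
    }
  }
  sts <- spike_train_set(spikes, unit_ids = seq_len(config$n_units),
                         trial_ids = trials$trial_id)

  # ---- kinematics --------------------------------------------------------
  kin <- lapply(seq_len(n_tr), function(k) {
    t <- seq(0, trials$t_end[k], by = 1 / config$kin_rate)
    ang <- direction[k] * pi / 180
    min_jerk_trace(t, t_start = t_move[k], duration = config$move_duration,
                   x1 = config$reach_radius * cos(ang),
                   y1 = config$reach_radius * sin(ang))
  })
  names(kin) <- as.character(trials$trial_id)

  list(spikes = sts, trials = trials, kinematics = kin,
       ground_truth = list(preferred_direction = pref,
                           pairs = assemblies$by_direction,
                           background = assemblies$background,
                           dip_window = config$dip_window,
                           injection_onset = config$tuning_latency),
       config = config)
}

# Injection bookkeeping. Two kinds of injected pairs:
#  * background: floor(assembly_size / 2) unordered pairs, both directions,
#    identical for every trial and active from trial start — the
#    direction-blind reciprocal scaffold of the network. A reciprocity_dip
#    fraction of them has the reverse leg silenced inside dip_window.
#  * by_direction: assembly_size unidirectional ordered pairs per target
#    direction (disjoint from the background), active post-Instruction —
#    the direction code.
make_assemblies <- function(config) {
  dirs8 <- seq(0, 315, by = 45)
  n <- config$n_units
  n_bi <- floor(config$assembly_size / 2)        # unordered reciprocal pairs
  unordered <- t(utils::combn(n, 2))
  if (n_bi > nrow(unordered) ||
      config$assembly_size + 2L * n_bi > n * (n - 1))
    stop("assembly_size too large for n_units")
  bi <- unordered[sample.int(nrow(unordered), n_bi), , drop = FALSE]
  n_sup <- round(config$reciprocity_dip * n_bi)
  background <- data.frame(
    src = c(bi[, 1], bi[, 2]), tgt = c(bi[, 2], bi[, 1]),
    bidirectional = TRUE,
    # the reverse leg of the first n_sup reciprocal pairs carries the dip
    dip_suppressed = c(rep(FALSE, n_bi), seq_len(n_bi) <= n_sup))
  ordered <- expand.grid(src = seq_len(n), tgt = seq_len(n))
  ordered <- ordered[ordered$src != ordered$tgt, ]
  free <- ordered[!paste(ordered$src, ordered$tgt) %in%
                    paste(background$src, background$tgt), ]
  by_direction <- lapply(dirs8, function(d) {
    uni <- free[sample.int(nrow(free), config$assembly_size), , drop = FALSE]
    rows <- data.frame(src = uni$src, tgt = uni$tgt, bidirectional = FALSE,
                       dip_suppressed = FALSE)
    rownames(rows) <- NULL
    rows
  })
  names(by_direction) <- as.character(dirs8)
  list(background = background, by_direction = by_direction)
}
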