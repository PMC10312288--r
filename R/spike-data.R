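#' Construct a spike train set
#'
#' A `spike_train_set` holds the spike times of every recorded unit on every
#' trial, in seconds relative to trial start (trial start is 0.5 s before the
#' Instruction cue). Spike times must be ascending within each (unit, trial)
#' train and non-negative.
#'
#' @param spikes nested list: `spikes[[u]][[k]]` is the numeric vector of
#'   spike times (s) of unit `u` on trial `k`; may be empty.
#' @param unit_ids character or integer vector of unique unit identifiers,
#'   one per element of `spikes`.
#' @param trial_ids vector of trial identifiers, one per inner element.
#' @return an object of class `spike_train_set` with fields `spikes`,
#'   `unit_ids`, `trial_ids`, `n_units`, `n_trials`.
#' @export
spike_train_set <- function(spikes, unit_ids, trial_ids) {
  if (length(spikes) != length(unit_ids))
    stop("one spike list per unit id required")
  if (anyDuplicated(unit_ids))
    stop("unit_ids must be unique")
  spikes <- lapply(spikes, function(per_unit) {
    if (length(per_unit) != length(trial_ids))
      stop("each unit needs one train per trial")
    lapply(per_unit, function(tr) {
      tr <- as.numeric(tr)
      if (length(tr) && any(diff(tr) < 0))
        stop("spike times must be ascending within a train")
      if (length(tr) && any(tr < 0))
        stop("spike times must be non-negative")
      tr
    })
  })
  structure(
    list(spikes = spikes, unit_ids = unit_ids, trial_ids = trial_ids,
         n_units = length(unit_ids), n_trials = length(trial_ids)),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_spk <- sum(vapply(x$spikes, function(u) sum(lengths(u)), numeric(1)))
  cat(sprintf("<spike_train_set> %d units x %d trials, %d spikes\n",
              x$n_units, x$n_trials, n_spk))
  invisible(x)
}

#' Spike trains of one trial
#'
#' @param sts a [spike_train_set()]
#' @param trial trial id
#' @return list of per-unit spike time vectors, in unit order
#' @export
trial_spikes <- function(sts, trial) {
  k <- match(trial, sts$trial_ids)
  if (is.na(k)) stop("unknown trial id: ", trial)
  lapply(sts$spikes, `[[`, k)
}

#' Restrict a spike train set to a subset of trials
#'
#' @param sts a [spike_train_set()]
#' @param trial_ids trials to keep (order preserved)
#' @return a [spike_train_set()] over the requested trials
#' @export
subset_spike_trials <- function(sts, trial_ids) {
  idx <- match(trial_ids, sts$trial_ids)
  if (anyNA(idx)) stop("unknown trial id(s)")
  spike_train_set(lapply(sts$spikes, function(u) u[idx]), sts$unit_ids,
                  trial_ids)
}

#' Construct a trial metadata table
#'
#' Event times are in seconds from trial start; the task is an
#' instructed-delay center-out reach with Instruction at 0.5 s, a 1-s delay,
#' then Go. `target_direction` is one of the 8 radial targets (degrees).
#'
#' @param trial_id,target_direction,t_instruction,t_go,t_movement_onset,t_acquisition,correct
#'   equal-length per-trial vectors; event times may be `NA` (e.g. aborted
#'   trials), in which case [filter_trials()] excludes the trial.
#' @param t_end optional trial end (defaults to `t_acquisition + 0.5`).
#' @return data.frame of class `trial_table` with an `included` flag
#'   (initialized `NA`; set by [filter_trials()]).
#' @export
trial_table <- function(trial_id, target_direction, t_instruction, t_go,
                        t_movement_onset, t_acquisition, correct,
                        t_end = t_acquisition + 0.5) {
  ok_dir <- is.na(target_direction) | target_direction %in% seq(0, 315, by = 45)
  if (!all(ok_dir))
    stop("target_direction must be one of 0,45,...,315 degrees")
  tt <- data.frame(trial_id = trial_id,
                   target_direction = as.numeric(target_direction),
                   t_instruction = as.numeric(t_instruction),
                   t_go = as.numeric(t_go),
                   t_movement_onset = as.numeric(t_movement_onset),
                   t_acquisition = as.numeric(t_acquisition),
                   t_end = as.numeric(t_end),
                   correct = as.logical(correct),
                   included = NA)
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Apply the trial inclusion rule
#'
#' A trial is included iff it is correct and the target was acquired within
#' 1.5 s of movement onset. Trials with missing event times or event times
#' out of order are excluded, with the reason recorded in an
#' `exclusion_reason` column.
#'
#' @param trials a [trial_table()]
#' @param max_acquisition_s acquisition deadline after movement onset
#'   (default 1.5 s).
#' @return the table with `included` and `exclusion_reason` filled in; event
#'   times are never modified.
#' @export
filter_trials <- function(trials, max_acquisition_s = 1.5) {
  reason <- rep(NA_character_, nrow(trials))
  times <- trials[, c("t_instruction", "t_go", "t_movement_onset",
                      "t_acquisition")]
  missing_t <- apply(is.na(times), 1, any)
  reason[missing_t] <- "missing event time"
  bad_order <- !missing_t &
    !(trials$t_instruction < trials$t_go &
      trials$t_go < trials$t_movement_onset &
      trials$t_movement_onset < trials$t_acquisition)
  reason[bad_order] <- "event times out of order"
  slow <- !missing_t & !bad_order &
    (trials$t_acquisition - trials$t_movement_onset) > max_acquisition_s
  reason[slow] <- "acquisition too slow"
  wrong <- is.na(reason) & !trials$correct
  reason[wrong] <- "incorrect trial"
  trials$included <- is.na(reason)
  trials$exclusion_reason <- reason
  trials
}

#' Trial ids passing the inclusion rule
#' @param trials a filtered [trial_table()]
#' @return vector of included trial ids
#' @export
included_trials <- function(trials) {
  if (all(is.na(trials$included)))
    trials <- filter_trials(trials)
  trials$trial_id[trials$included]
}
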