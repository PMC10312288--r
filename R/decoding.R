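#' Assemble decoder features for one time window
#'
#' One sample per included trial, for a 200-ms window whose *trailing* edge
#' sits `offset` seconds after the alignment event (causal convention, as in
#' [build_temporal_fn()]). Feature sets:
#' \describe{
#'   \item{FR}{per-unit spike counts in the window (length N)}
#'   \item{FN}{vectorized off-diagonal conMI weights (length N(N-1))}
#'   \item{FRFN}{concatenation, FR first (length N + N(N-1))}
#'   \item{nullFN}{FN features computed from one rate-matched surrogate
#'     realization per trial}
#' }
#'
#' @param sts a [spike_train_set()]
#' @param trials a filtered [trial_table()]
#' @param offset trailing-edge time of the window relative to `align_event`
#'   (s)
#' @param mode one of `"FR"`, `"FN"`, `"FRFN"`, `"nullFN"`
#' @param align_event `"instruction"`, `"go"`, `"movement"`, or `"start"`
#' @param window window length (s, default 0.200)
#' @param bin_width bin width (s, default 0.010)
#' @param surrogate_seed seed for the `nullFN` surrogate draw
#' @return list with `x` (samples x features matrix), `y` (factor of target
#'   directions), `trial_ids`
#' @export
assemble_features <- function(sts, trials, offset, mode, align_event = "instruction",
                              window = 0.200, bin_width = 0.010,
                              surrogate_seed = 1L) {
  if (!mode %in% c("FR", "FN", "FRFN", "nullFN"))
    stop("unknown feature mode: ", mode)
  ids <- included_trials(trials)
  use <- if (mode == "nullFN")
    surrogate_spike_trains(sts, trials, seed = surrogate_seed) else sts
  n <- use$n_units
  off_diag <- as.vector(t(row(diag(n)) != col(diag(n)))) # row-major mask
  rows <- lapply(ids, function(id) {
    k <- match(id, trials$trial_id)
    a <- switch(align_event, start = 0,
                instruction = trials$t_instruction[k], go = trials$t_go[k],
                movement = trials$t_movement_onset[k],
                stop("unknown align_event: ", align_event))
    t0 <- a + offset - window
    tr <- trial_spikes(use, id)
    fr <- vapply(tr, function(s) sum(s >= t0 & s < t0 + window), numeric(1))
    if (mode == "FR") return(fr)
    raster <- bin_spikes(tr, t0, window, bin_width)
    fn <- vectorize_fn(conmi_matrix(raster))[off_diag]
    switch(mode, FN = fn, nullFN = fn, FRFN = c(fr, fn))
  })
  list(x = do.call(rbind, rows),
       y = factor(trials$target_direction[match(ids, trials$trial_id)]),
       trial_ids = ids)
}

#' Train one decoder and score it on held-out data
#'
#' Stratified 75/25 train/test split, then the standard MLP decoder
#' ([mlp_fit()]: 100 ReLU hidden units, step size 0.001, at most 200
#' iterations). The seed fixes both the split and the weight
#' initialization.
#'
#' @param x feature matrix (samples x features)
#' @param y labels
#' @param seed integer seed
#' @param train_frac training fraction (default 0.75)
#' @param ... passed to [mlp_fit()]
#' @return held-out accuracy in `[0, 1]`
#' @export
train_and_score <- function(x, y, seed = 1L, train_frac = 0.75, ...) {
  y <- factor(y)
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  set.seed(seed)
  train <- unlist(lapply(split(seq_along(y), y), function(idx) {
    n_tr <- round(train_frac * length(idx))
    sample(idx, n_tr)
  }), use.names = FALSE)
  test <- setdiff(seq_along(y), train)
  fit <- mlp_fit(x[train, , drop = FALSE], y[train], seed = seed + 1L, ...)
  mean(predict(fit, x[test, , drop = FALSE]) == y[test])
}

#' Decoding-performance timeline
#'
#' For every window time and feature set, trains and tests `n_repeats`
#' decoders (independent stratified splits and initializations) predicting
#' the instructed reach target, giving a distribution of held-out accuracy
#' per cell.
#'
#' @param sts a [spike_train_set()]
#' @param trials a filtered [trial_table()]
#' @param offsets window trailing-edge times relative to `align_event` (s)
#' @param modes subset of `c("FR", "FN", "FRFN", "nullFN")`
#' @param align_event alignment event (default `"instruction"`)
#' @param n_repeats decoders per cell (default 50)
#' @param seed master seed (substreams per window, mode, repeat)
#' @param window,bin_width window geometry
#' @return data.frame of class `decoder_result`: columns `time`, `mode`,
#'   `rep`, `accuracy`; attribute `chance` = 1 / number of classes
#' @export
decoding_timeline <- function(sts, trials, offsets,
                              modes = c("FR", "FN", "FRFN", "nullFN"),
                              align_event = "instruction", n_repeats = 50L,
                              seed = 1L, window = 0.200, bin_width = 0.010) {
  out <- list()
  for (w in seq_along(offsets)) {
    for (mode in modes) {
      feats <- assemble_features(sts, trials, offsets[w], mode,
                                 align_event = align_event, window = window,
                                 bin_width = bin_width,
                                 surrogate_seed = derive_seed(seed, w, 99L))
      acc <- vapply(seq_len(n_repeats), function(r)
        train_and_score(feats$x, feats$y,
                        seed = derive_seed(seed, w, match(mode, modes), r)),
        numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        time = offsets[w], mode = mode, rep = seq_len(n_repeats),
        accuracy = acc)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "chance") <- 1 / nlevels(factor(trials$target_direction))
  class(res) <- c("decoder_result", "data.frame")
  res
}

#' Decoding onset and initial peak
#'
#' Onset: the first window whose accuracy distribution beats chance
#' (one-sample t test, one-sided, p < alpha Bonferroni-corrected over the
#' windows of the epoch) *and* that starts a run of at least
#' `sustain` consecutive significant windows. Peak: the window with maximal
#' mean accuracy within `peak_within` seconds after the alignment event.
#'
#' @param result a [decoding_timeline()] result (single mode, or use
#'   `mode` to select one)
#' @param chance chance level (default 0.125 for 8 targets)
#' @param mode feature set to analyze (default: the only one present)
#' @param alpha significance level before correction (default 0.01)
#' @param sustain required run length (default 3)
#' @param peak_within peak search horizon after the event (s, default 0.5)
#' @return list with `onset` (time or `NA`), `peak_time`, `peak_value`
#'   (mean accuracy), and the per-window p-values
#' @export
find_onset_and_peak <- function(result, chance = 0.125, mode = NULL,
                                alpha = 0.01, sustain = 3L,
                                peak_within = 0.5) {
  if (!is.null(mode)) result <- result[result$mode == mode, ]
  if (length(unique(result$mode)) != 1)
    stop("select a single feature mode")
  times <- sort(unique(result$time))
  pvals <- vapply(times, function(tt) {
    acc <- result$accuracy[result$time == tt]
    if (stats::sd(acc) == 0) return(if (mean(acc) > chance) 0 else 1)
    stats::t.test(acc, mu = chance, alternative = "greater")$p.value
  }, numeric(1))
  sig <- pvals < alpha / length(times)
  onset <- NA_real_
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  good <- which(runs$values & runs$lengths >= sustain)
  if (length(good))
    onset <- times[ends[good[1]] - runs$lengths[good[1]] + 1L]
  in_peak <- times > 0 & times <= peak_within
  means <- vapply(times, function(tt)
    mean(result$accuracy[result$time == tt]), numeric(1))
  peak_idx <- if (any(in_peak)) which(in_peak)[which.max(means[in_peak])] else
    which.max(means)
  list(onset = onset, peak_time = times[peak_idx],
       peak_value = means[peak_idx], p_values = pvals, times = times)
}
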