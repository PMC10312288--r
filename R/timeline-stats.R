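#' Window-wise Mann-Whitney significance timeline
#'
#' Two-sided Mann-Whitney U test between two groups of scores at every
#' window, Bonferroni-corrected with family size = number of windows in the
#' aligned epoch. Used to ask when, e.g., same-direction and
#' opposite-direction alignment-score distributions diverge.
#'
#' @param group_a,group_b lists of numeric score vectors, one per window
#'   (equal length lists; names or the `times` argument give window times)
#' @param times window times (default: indices)
#' @param alpha uncorrected significance level (default 0.01)
#' @return data.frame of class `significance_timeline` with columns `time`,
#'   `statistic`, `p`, `p_threshold`, `significant`, `family_size`,
#'   `testable`
#' @export
mwu_timeline <- function(group_a, group_b, times = seq_along(group_a),
                         alpha = 0.01) {
  if (length(group_a) != length(group_b))
    stop("groups must cover the same windows")
  fam <- length(group_a)
  rows <- lapply(seq_len(fam), function(w) {
    a <- group_a[[w]]
    b <- group_b[[w]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(time = times[w], statistic = NA_real_, p = NA_real_,
                        p_threshold = alpha / fam, significant = FALSE,
                        family_size = fam, testable = FALSE))
    ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                              exact = FALSE))
    data.frame(time = times[w], statistic = unname(ht$statistic),
               p = ht$p.value, p_threshold = alpha / fam,
               significant = ht$p.value < alpha / fam, family_size = fam,
               testable = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("significance_timeline", "data.frame")
  out
}

#' First sustained divergence time
#'
#' The first window that is significant and begins a run of at least
#' `sustain` consecutive significant windows ("significantly different from
#' X ms onward"); `NA` when no such run exists.
#'
#' @param timeline a [mwu_timeline()] result (windows ordered by time)
#' @param sustain required run length (default 3)
#' @return divergence time, or `NA`
#' @export
detect_divergence_time <- function(timeline, sustain = 3L) {
  timeline <- timeline[order(timeline$time), ]
  sig <- timeline$significant & timeline$testable
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  good <- which(runs$values & runs$lengths >= sustain)
  if (!length(good)) return(NA_real_)
  timeline$time[ends[good[1]] - runs$lengths[good[1]] + 1L]
}

#' Reciprocity baseline comparison
#'
#' The baseline distribution is each trial's mean normalized reciprocity over
#' the windows from the Instruction cue to 100 ms post-Instruction. Each
#' window's per-trial scores are compared against that baseline with an
#' independent-sample t test (Bonferroni-corrected over windows); the window
#' of minimum mean reciprocity is reported with its own uncorrected test, as
#' in the starred minima of the reciprocity figure.
#'
#' @param timeline a [reciprocity_timeline()] data.frame (times relative to
#'   Instruction), optionally restricted to one percentile; if several
#'   percentiles are present they are averaged per trial and window first
#' @param baseline_window `c(lo, hi)` in s post-Instruction (default
#'   `c(0, 0.1)`)
#' @param alpha uncorrected level (default 0.01)
#' @return list with `baseline` (per-trial means), `windows` (per-window
#'   time, mean rho, p, corrected significance), `dip_windows` (times
#'   significantly *below* baseline after correction), `minimum_time`,
#'   `minimum_p` (uncorrected), `minimum_significant`
#' @export
reciprocity_baseline_test <- function(timeline, baseline_window = c(0, 0.1),
                                      alpha = 0.01) {
  agg <- stats::aggregate(rho ~ trial + time, data = timeline, FUN = mean,
                          na.action = stats::na.omit)
  in_base <- agg$time >= baseline_window[1] & agg$time <= baseline_window[2]
  if (!any(in_base)) stop("baseline window contains no windows")
  baseline <- tapply(agg$rho[in_base], agg$trial[in_base], mean)
  baseline <- baseline[!is.na(baseline)]
  times <- sort(unique(agg$time))
  fam <- length(times)
  test_one <- function(tt) {
    sc <- agg$rho[agg$time == tt]
    sc <- sc[!is.na(sc)]
    if (length(sc) < 2 || stats::sd(c(sc, baseline)) == 0)
      return(c(mean = mean(sc), p = NA_real_))
    ht <- stats::t.test(sc, baseline, var.equal = FALSE)
    c(mean = mean(sc), p = ht$p.value)
  }
  res <- t(vapply(times, test_one, numeric(2)))
  windows <- data.frame(time = times, mean_rho = res[, "mean"],
                        p = res[, "p"],
                        significant = !is.na(res[, "p"]) &
                          res[, "p"] < alpha / fam)
  below <- windows$significant & windows$mean_rho < mean(baseline)
  min_idx <- which.min(windows$mean_rho)   # earliest among exact ties
  min_sc <- agg$rho[agg$time == times[min_idx]]
  min_sc <- min_sc[!is.na(min_sc)]
  min_p <- if (length(min_sc) >= 2 && stats::sd(c(min_sc, baseline)) > 0)
    stats::t.test(min_sc, baseline, var.equal = FALSE)$p.value else NA_real_
  list(baseline = baseline, windows = windows,
       dip_windows = windows$time[below],
       minimum_time = windows$time[min_idx], minimum_p = min_p,
       minimum_significant = !is.na(min_p) && min_p < alpha &&
         windows$mean_rho[min_idx] < mean(baseline))
}

#' Per-window GAS score groups for timeline testing
#'
#' Reshapes temporal-FN alignment scores into the per-window score lists
#' consumed by [mwu_timeline()]: for each window, the GAS of every trial
#' pair, grouped by target-direction difference.
#'
#' @param tfns list of `temporal_fn` objects, one per trial (shared window
#'   grid)
#' @param directions target direction per trial (degrees)
#' @return list with `times` and `groups`: `groups[[delta]][[window]]` is a
#'   numeric vector of scores, for delta in `"0","45","90","135","180"`
#' @export
gas_timeline_groups <- function(tfns, directions) {
  times <- tfns[[1]]$times
  n <- length(tfns)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  delta <- circular_delta(directions[pairs[, 1]], directions[pairs[, 2]])
  deltas <- c(0, 45, 90, 135, 180)
  groups <- lapply(deltas, function(d) {
    sel <- which(delta == d)
    lapply(seq_along(times), function(w)
      vapply(sel, function(p)
        graph_alignment_score(tfns[[pairs[p, 1]]]$fns[[w]],
                              tfns[[pairs[p, 2]]]$fns[[w]]),
        numeric(1)))
  })
  names(groups) <- as.character(deltas)
  list(times = times, groups = groups)
}
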