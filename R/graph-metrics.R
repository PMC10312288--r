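#' Graph alignment score between two weighted networks
#'
#' Node-identity-preserving overlap ratio between two non-negative weighted
#' networks on the same node set:
#' \deqn{\mathrm{GAS} = \frac{2 \sum_{ij} \min(M_{ij}, N_{ij})}
#'   {\sum_{ij} (M_{ij} + N_{ij})}}
#' summed over all ordered pairs. 1 means the two networks are identical;
#' 0 means disjoint edge support. Symmetric in its arguments and invariant
#' to a common rescaling of both networks.
#'
#' @param m,n [functional_network()] objects or non-negative square matrices
#'   with identical node order
#' @return scalar in `[0, 1]`
#' @export
graph_alignment_score <- function(m, n) {
  wm <- if (inherits(m, "functional_network")) m$weights else as.matrix(m)
  wn <- if (inherits(n, "functional_network")) n$weights else as.matrix(n)
  if (!identical(dim(wm), dim(wn))) stop("networks must have the same size")
  if (inherits(m, "functional_network") && inherits(n, "functional_network") &&
      !identical(m$unit_ids, n$unit_ids))
    stop("networks must share the same unit order")
  if (any(wm < 0) || any(wn < 0)) stop("weights must be non-negative")
  diag(wm) <- 0
  diag(wn) <- 0
  denom <- sum(wm) + sum(wn)
  if (denom == 0) stop("GAS undefined: both networks are all-zero")
  2 * sum(pmin(wm, wn)) / denom
}

#' Pairwise GAS grouped by reach-target separation
#'
#' Computes the alignment score for every unordered pair of trials and bins
#' the pairs by the circular angular difference between their instructed
#' targets, so with 8 radial targets the groups are
#' Delta in \{0, 45, 90, 135, 180\} degrees.
#'
#' @param fns list of [functional_network()] objects, one per trial
#' @param directions target direction (degrees) per FN
#' @return data.frame of class `gas_distribution` with columns `trial_a`,
#'   `trial_b`, `delta`, `gas`
#' @export
group_gas_by_target_delta <- function(fns, directions) {
  if (length(fns) != length(directions))
    stop("one direction per network required")
  n <- length(fns)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  delta <- circular_delta(directions[pairs[, 1]], directions[pairs[, 2]])
  gas <- vapply(seq_len(nrow(pairs)), function(p)
    graph_alignment_score(fns[[pairs[p, 1]]], fns[[pairs[p, 2]]]),
    numeric(1))
  out <- data.frame(trial_a = pairs[, 1], trial_b = pairs[, 2],
                    delta = delta, gas = gas)
  class(out) <- c("gas_distribution", "data.frame")
  out
}

#' Circular distance between reach directions
#' @param a,b directions in degrees
#' @return minimum of clockwise / counterclockwise separation, in `[0, 180]`
#' @export
circular_delta <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Threshold a network at a weight percentile
#'
#' Keeps the most reliable interactions: edges whose weight is at least the
#' given percentile of the network's *nonzero off-diagonal* weights survive;
#' all others are set to zero. Ties at the threshold are kept, so a
#' percentile of 0 leaves the network unchanged and an all-equal network
#' survives intact at any percentile. The percentile is computed per network
#' (not pooled across networks).
#'
#' @param fn a [functional_network()] or matrix
#' @param percentile in `[0, 100)`; e.g. 85 keeps roughly the top 15% of
#'   magnitudes
#' @return same type as `fn`, thresholded
#' @export
threshold_fn_by_percentile <- function(fn, percentile) {
  if (percentile < 0 || percentile >= 100)
    stop("percentile must be in [0, 100)")
  w <- if (inherits(fn, "functional_network")) fn$weights else as.matrix(fn)
  nz <- w[w > 0 & row(w) != col(w)]
  if (!length(nz)) stop("network has no nonzero off-diagonal edge")
  thr <- stats::quantile(nz, percentile / 100, names = FALSE, type = 7)
  w[w < thr] <- 0
  diag(w) <- 0
  if (inherits(fn, "functional_network")) {
    fn$weights <- w
    fn
  } else w
}

#' Weighted reciprocity of a directed network
#'
#' The fraction of total edge weight that is bidirectional: each ordered
#' pair contributes its reciprocated weight `min(w_ij, w_ji)`, so
#' \deqn{r = \frac{W^\leftrightarrow}{W},\quad
#'   W^\leftrightarrow = \sum_{i}\sum_{j \ne i} \min(w_{ij}, w_{ji}),\quad
#'   W = \sum_{i}\sum_{j \ne i} w_{ij}.}
#' A symmetric network has r = 1; a network with no reciprocated weight has
#' r = 0. Invariant to global rescaling.
#'
#' @param fn a [functional_network()] or non-negative square matrix with zero
#'   diagonal
#' @return scalar in `[0, 1]`
#' @export
weighted_reciprocity <- function(fn) {
  w <- if (inherits(fn, "functional_network")) fn$weights else as.matrix(fn)
  diag(w) <- 0
  W <- sum(w)
  if (W == 0) stop("reciprocity undefined: total edge weight is zero")
  sum(pmin(w, t(w))) / W
}

#' Surrogate-normalized reciprocity
#'
#' Normalizes an observed reciprocity `r` against the mean reciprocity
#' `r_bar` of rate-matched surrogate networks:
#' \deqn{\rho = \frac{r - \bar r}{1 - \bar r}.}
#' Positive when the data are more reciprocal than expected from firing
#' rates alone, negative when less; 1 iff `r = 1`.
#'
#' @param r observed reciprocity
#' @param r_bar mean surrogate reciprocity (must be < 1)
#' @return normalized reciprocity, at most 1
#' @export
normalized_reciprocity <- function(r, r_bar) {
  if (any(r_bar >= 1)) stop("normalization undefined when r_bar = 1")
  (r - r_bar) / (1 - r_bar)
}

#' Reciprocity timeline of temporal networks with surrogate normalization
#'
#' For each threshold percentile, trial, and window: thresholds the data FN,
#' measures `r`, thresholds each surrogate FN identically, averages their
#' reciprocity into `r_bar` (per trial and window), and reports
#' `rho = (r - r_bar)/(1 - r_bar)`. Windows where a thresholded network has
#' no weight yield `NA`.
#'
#' @param tfns list of `temporal_fn` objects (data), one per trial
#' @param null_tfns list over surrogate iterations, each a list of
#'   `temporal_fn` objects parallel to `tfns` (e.g. 45 iterations)
#' @param percentiles threshold percentiles (default `85:90`)
#' @return data.frame of class `reciprocity_timeline` with columns
#'   `percentile`, `trial`, `time`, `r`, `r_bar`, `rho`
#' @export
reciprocity_timeline <- function(tfns, null_tfns, percentiles = 85:90) {
  times <- tfns[[1]]$times
  safe_r <- function(fn, p) {
    tryCatch(weighted_reciprocity(threshold_fn_by_percentile(fn, p)),
             error = function(e) NA_real_)
  }
  out <- list()
  for (p in percentiles) {
    for (tr in seq_along(tfns)) {
      r <- vapply(tfns[[tr]]$fns, safe_r, numeric(1), p = p)
      null_r <- vapply(null_tfns, function(iter)
        vapply(iter[[tr]]$fns, safe_r, numeric(1), p = p),
        numeric(length(times)))
      r_bar <- rowMeans(matrix(null_r, nrow = length(times)), na.rm = TRUE)
      rho <- ifelse(is.na(r) | is.na(r_bar) | r_bar >= 1, NA_real_,
                    (r - r_bar) / (1 - r_bar))
      out[[length(out) + 1L]] <- data.frame(
        percentile = p, trial = tfns[[tr]]$trial_id, time = tfns[[tr]]$times,
        r = r, r_bar = r_bar, rho = rho)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("reciprocity_timeline", "data.frame")
  out
}
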