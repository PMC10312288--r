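#' Confluent mutual information between two binary spike sequences
#'
#' conMI quantifies how much the firing state of a source unit `i` in bin `t`
#' tells us about the firing state of a target unit `j` in the *same or the
#' next* bin: the target sequence is collapsed to
#' `j_hat[t] = 1 iff j[t] == 1 OR j[t+1] == 1`, and the plug-in mutual
#' information between `i[t]` and `j_hat[t]` is returned in bits,
#'
#' \deqn{\mathrm{conMI} = \sum_{i_t \in \{0,1\}} \sum_{\hat j_t \in \{0,1\}}
#'   p(i_t, \hat j_t) \log_2 \frac{p(i_t, \hat j_t)}{p(i_t) p(\hat j_t)}.}
#'
#' Probabilities are empirical frequencies over `t = 1..T-1` (the final bin
#' is dropped because `j_hat` needs `t+1`). The measure is asymmetric in
#' `(x, y)`, hence yields directed edges. Conventions: `0 log 0 = 0`; if
#' either marginal is degenerate (all 0 or all 1) the result is exactly 0.
#'
#' @param x binary source sequence (0/1), length T >= 2
#' @param y binary target sequence, same length
#' @return conMI in bits (non-negative)
#' @export
confluent_mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("sequences must have length >= 2")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("sequences must be binary (0/1)")
  Tn <- length(x) - 1L
  xs <- x[seq_len(Tn)]
  yhat <- as.integer(y[seq_len(Tn)] | y[seq_len(Tn) + 1L])
  n11 <- sum(xs & yhat)
  n1 <- sum(xs)
  m1 <- sum(yhat)
  conmi_from_counts(n11, n1, m1, Tn)
}

# plug-in MI (bits) of a 2x2 table given n(source=1,target=1), the two
# marginal one-counts and the sample count; vector-safe
conmi_from_counts <- function(n11, n1, m1, Tn) {
  n10 <- n1 - n11
  n01 <- m1 - n11
  n00 <- Tn - n11 - n10 - n01
  term <- function(nab, na, nb) {
    out <- numeric(length(nab))
    pos <- nab > 0 & na > 0 & nb > 0
    out[pos] <- (nab[pos] / Tn) * log2(nab[pos] * Tn / (na[pos] * nb[pos]))
    out
  }
  v <- term(n11, n1, m1) + term(n10, n1, Tn - m1) +
    term(n01, Tn - n1, m1) + term(n00, Tn - n1, Tn - m1)
  pmax(v, 0) # clip tiny negative float residue
}

#' All-pairs conMI matrix of a binned raster
#'
#' Entry `(i, j)` is conMI with unit `i` as source and unit `j` as target;
#' the diagonal is identically zero. Computed from joint bin counts by
#' matrix products, so it scales to hundreds of units.
#'
#' @param raster a [bin_spikes()] raster (units x bins)
#' @return N x N non-negative matrix in bits
#' @export
conmi_matrix <- function(raster) {
  m <- raster$matrix
  if (nrow(m) < 2) stop("need at least 2 units")
  if (ncol(m) < 2) stop("need at least 2 bins")
  Tn <- ncol(m) - 1L
  src <- m[, seq_len(Tn), drop = FALSE]
  tgt <- (m[, seq_len(Tn), drop = FALSE] | m[, seq_len(Tn) + 1L, drop = FALSE])
  storage.mode(tgt) <- "double"
  storage.mode(src) <- "double"
  n11 <- src %*% t(tgt)                    # joint one-counts, source x target
  n1 <- rowSums(src)
  m1 <- rowSums(tgt)
  w <- matrix(conmi_from_counts(as.vector(n11),
                                rep(n1, times = ncol(n11)),
                                rep(m1, each = nrow(n11)),
                                Tn),
              nrow = nrow(m))
  diag(w) <- 0
  w
}

#' Construct a functional network object
#'
#' @param weights N x N non-negative matrix, zero diagonal; entry `(i, j)` is
#'   the conMI of source `i` about target `j` (bits)
#' @param unit_ids node identifiers (order fixed across all FNs of a session)
#' @param window `c(t0, duration)` of the data window (s)
#' @param trial_id originating trial (or `NA`)
#' @return object of class `functional_network`
#' @export
functional_network <- function(weights, unit_ids = seq_len(nrow(weights)),
                               window = c(NA_real_, NA_real_),
                               trial_id = NA) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (length(unit_ids) != nrow(weights))
    stop("one unit id per node required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  structure(list(weights = weights, unit_ids = unit_ids,
                 window = as.numeric(window), trial_id = trial_id),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d units, %d nonzero edges",
              nrow(x$weights), sum(x$weights > 0)))
  if (!is.na(x$window[1]))
    cat(sprintf(", window [%.3f, %.3f) s", x$window[1],
                x$window[1] + x$window[2]))
  cat("\n")
  invisible(x)
}

#' Full-trial functional network
#'
#' conMI between every ordered pair of units over the whole trial raster.
#'
#' @param raster a [bin_spikes()] raster covering the trial
#' @param unit_ids node identifiers
#' @param trial_id originating trial
#' @return a [functional_network()]
#' @export
build_full_trial_fn <- function(raster, unit_ids = seq_len(nrow(raster$matrix)),
                                trial_id = NA) {
  functional_network(conmi_matrix(raster), unit_ids = unit_ids,
                     window = c(raster$t0,
                                ncol(raster$matrix) * raster$bin_width),
                     trial_id = trial_id)
}

#' Temporal functional network of one trial
#'
#' conMI networks for 200-ms windows slid in 10-ms (one-bin) steps across the
#' trial. Each window FN is computed on its own 20-bin raster. Window
#' timestamps (`$times`) are the *trailing* (right) edge of the window
#' relative to `align_time`, so the FN stamped at 160 ms uses only data up to
#' 160 ms (causal convention; see the methods vignette).
#'
#' @param trains list of per-unit spike time vectors for one trial
#' @param t_start,t_stop analyzed extent (s, trial clock)
#' @param window window length (s, default 0.200)
#' @param step window increment (s, default 0.010)
#' @param bin_width bin width (s, default 0.010)
#' @param align_time event time subtracted from timestamps (default 0)
#' @param unit_ids,trial_id metadata
#' @return object of class `temporal_fn`: list with `fns` (one
#'   [functional_network()] per window), `times`, `window`, `step`,
#'   `align_time`
#' @export
build_temporal_fn <- function(trains, t_start, t_stop, window = 0.200,
                              step = 0.010, bin_width = 0.010, align_time = 0,
                              unit_ids = seq_along(trains), trial_id = NA) {
  duration <- t_stop - t_start
  if (duration < window - 1e-9) stop("trial shorter than one window")
  n_win <- floor((duration - window) / step + 1e-9) + 1L
  # bin once over the whole extent; each window is a 20-column slice
  full <- bin_spikes(trains, t_start, duration, bin_width)
  bins_per_win <- round(window / bin_width)
  bins_per_step <- round(step / bin_width)
  fns <- vector("list", n_win)
  times <- numeric(n_win)
  for (w in seq_len(n_win)) {
    first <- (w - 1L) * bins_per_step + 1L
    cols <- first:(first + bins_per_win - 1L)
    sub <- structure(list(matrix = full$matrix[, cols, drop = FALSE],
                          bin_width = bin_width,
                          t0 = t_start + (first - 1L) * bin_width),
                     class = "binned_raster")
    fns[[w]] <- build_full_trial_fn(sub, unit_ids = unit_ids,
                                    trial_id = trial_id)
    times[w] <- sub$t0 + window - align_time
  }
  structure(list(fns = fns, times = times, window = window, step = step,
                 align_time = align_time, trial_id = trial_id),
            class = "temporal_fn")
}

#' @export
print.temporal_fn <- function(x, ...) {
  cat(sprintf(
    "<temporal_fn> %d windows of %.0f ms (step %.0f ms), t = [%.3f, %.3f] s\n",
    length(x$fns), x$window * 1000, x$step * 1000, min(x$times), max(x$times)))
  invisible(x)
}

#' Vectorize a functional network
#'
#' Row-major flattening of the full N x N adjacency (diagonal zeros
#' retained), length N^2 — the representation embedded and decoded
#' downstream. [devectorize_fn()] inverts it.
#'
#' @param fn a [functional_network()] or a plain square matrix
#' @return numeric vector of length N^2
#' @export
vectorize_fn <- function(fn) {
  w <- if (inherits(fn, "functional_network")) fn$weights else as.matrix(fn)
  as.vector(t(w)) # t() because R stores column-major and we flatten row-major
}

#' Restore a matrix from [vectorize_fn()] output
#' @param v length-N^2 vector
#' @return N x N matrix
#' @export
devectorize_fn <- function(v) {
  n <- sqrt(length(v))
  if (n != round(n)) stop("length is not a perfect square")
  matrix(v, nrow = n, byrow = TRUE)
}
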