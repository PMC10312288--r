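#' Bin spike trains into a binary raster
#'
#' Spikes are assigned to 10-ms bins (the resolution at which pairwise
#' spike-time statistics are computed); a bin is 1 if at least one spike
#' falls in it and 0 otherwise. Bins are half-open `[left, right)`: a spike
#' exactly on a boundary belongs to the later bin. Spikes outside
#' `[t0, t0 + duration)` are ignored.
#'
#' @param trains list of per-unit spike time vectors (s), or a single vector
#'   for a one-unit raster.
#' @param t0 window start (s)
#' @param duration window duration (s); must be a positive multiple of
#'   `bin_width` (up to floating point).
#' @param bin_width bin width in seconds (default 0.010)
#' @return object of class `binned_raster`: integer `matrix` (units x bins)
#'   with attributes, fields `matrix`, `bin_width`, `t0`.
#' @export
bin_spikes <- function(trains, t0, duration, bin_width = 0.010) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (duration <= 0) stop("duration must be positive")
  n_bins <- floor(duration / bin_width + 1e-9)
  if (n_bins < 1) stop("duration shorter than one bin")
  if (!is.list(trains)) trains <- list(trains)
  m <- matrix(0L, nrow = length(trains), ncol = n_bins)
  for (u in seq_along(trains)) {
    tr <- trains[[u]]
    # half-open bins: floor((t - t0)/width) with boundary spikes rounding up
    idx <- floor((tr - t0) / bin_width + 1e-9) + 1L
    idx <- idx[idx >= 1L & idx <= n_bins]
    m[u, unique(idx)] <- 1L
  }
  structure(list(matrix = m, bin_width = bin_width, t0 = t0),
            class = "binned_raster")
}

#' @export
print.binned_raster <- function(x, ...) {
  cat(sprintf("<binned_raster> %d units x %d bins (%.0f ms bins, t0=%.3f s)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_width * 1000, x$t0))
  invisible(x)
}

#' Reconstruct a bin-center spike train from a raster row
#'
#' Inverse of [bin_spikes()] up to within-bin timing: each occupied bin
#' yields one spike at the bin center, so re-binning returns the same raster.
#'
#' @param raster a `binned_raster`
#' @param unit row index
#' @return numeric vector of bin-center times (s)
#' @export
raster_to_spikes <- function(raster, unit = 1L) {
  occupied <- which(raster$matrix[unit, ] == 1L)
  raster$t0 + (occupied - 0.5) * raster$bin_width
}

#' Raster of one trial (all units)
#'
#' @param sts a [spike_train_set()]
#' @param trial trial id
#' @param t0,duration window (defaults: full trial `[0, t_end)` when a
#'   `trial_table` is given)
#' @param trials optional [trial_table()] supplying the trial duration
#' @param bin_width bin width (s)
#' @return a `binned_raster` with one row per unit
#' @export
trial_raster <- function(sts, trial, t0 = 0, duration = NULL, trials = NULL,
                         bin_width = 0.010) {
  if (is.null(duration)) {
    if (is.null(trials)) stop("duration or a trial_table is required")
    duration <- trials$t_end[match(trial, trials$trial_id)] - t0
  }
  bin_spikes(trial_spikes(sts, trial), t0, duration, bin_width)
}
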