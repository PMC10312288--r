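#' Construct a 2D hand-kinematics trace
#'
#' @param t sample times (s), uniformly spaced
#' @param x,y hand position (m)
#' @return object of class `kinematics_trace` with fields `t`, `x`, `y`,
#'   `sampling_rate`
#' @export
kinematics_trace <- function(t, x, y) {
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (length(t) >= 3) {
    dt <- diff(t)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-12)
      stop("sampling must be uniform")
  }
  structure(list(t = t, x = x, y = y,
                 sampling_rate = if (length(t) >= 2) 1 / mean(diff(t)) else NA),
            class = "kinematics_trace")
}

#' Hand speed by central finite differences
#'
#' Speed is the Euclidean norm of the central-difference velocity,
#' optionally smoothed with a centered moving average. Endpoints use one-sided
#' differences.
#'
#' @param kin a [kinematics_trace()]
#' @param smooth_samples moving-average width (samples; 1 = no smoothing)
#' @return numeric vector of speeds (m/s), same length as `kin$t`
#' @export
hand_speed <- function(kin, smooth_samples = 5L) {
  n <- length(kin$t)
  if (n < 2) stop("trace too short")
  dt <- mean(diff(kin$t))
  vx <- c(diff(kin$x[1:2]), (kin$x[-(1:2)] - kin$x[1:(n - 2)]) / 2,
          diff(kin$x[(n - 1):n])) / dt
  vy <- c(diff(kin$y[1:2]), (kin$y[-(1:2)] - kin$y[1:(n - 2)]) / 2,
          diff(kin$y[(n - 1):n])) / dt
  sp <- sqrt(vx^2 + vy^2)
  k <- as.integer(smooth_samples)
  if (k > 1) {
    kern <- rep(1 / k, k)
    sp <- as.numeric(stats::filter(sp, kern, sides = 2))
    # moving average is undefined at the edges; fall back to raw speed there
    sp[is.na(sp)] <- sqrt(vx^2 + vy^2)[is.na(sp)]
  }
  sp
}

#' Detect movement onset from hand kinematics
#'
#' Movement onset is the earliest time after the Go cue at which hand speed
#' reaches 5% of the peak speed of the movement (peak taken after Go). The
#' threshold is relative, so onset is invariant to uniform speed rescaling.
#'
#' @param kin a [kinematics_trace()]
#' @param t_go Go-cue time (s)
#' @param threshold_frac fraction of post-Go peak speed (default 0.05)
#' @param smooth_samples smoothing passed to [hand_speed()]
#' @return onset time (s)
#' @export
detect_movement_onset <- function(kin, t_go, threshold_frac = 0.05,
                                  smooth_samples = 5L) {
  if (max(kin$t) <= t_go) stop("trace does not extend beyond t_go")
  sp <- hand_speed(kin, smooth_samples)
  post <- which(kin$t > t_go)
  peak <- max(sp[post])
  if (peak <= 0) stop("no movement detected: peak speed after Go is zero")
  hit <- post[sp[post] >= threshold_frac * peak]
  kin$t[hit[1]]
}

#' Minimum-jerk point-to-point reach
#'
#' Standard minimum-jerk position profile from `(x0, y0)` to `(x1, y1)` over
#' `[t_start, t_start + duration]`; flat before and after. Used by the
#' synthetic cohort generator to emulate center-out hand paths.
#'
#' @param t sample times (s)
#' @param t_start movement start (s)
#' @param duration movement duration (s)
#' @param x0,y0,x1,y1 start and end positions (m)
#' @return a [kinematics_trace()]
#' @export
min_jerk_trace <- function(t, t_start, duration, x0 = 0, y0 = 0, x1, y1) {
  tau <- pmin(pmax((t - t_start) / duration, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  kinematics_trace(t, x0 + (x1 - x0) * s, y0 + (y1 - y0) * s)
}
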