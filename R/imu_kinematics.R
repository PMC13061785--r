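# Kinematics from a two-axis accelerometer: angle conversion, cycle
# segmentation and cadence estimation. Angles are degrees in (-180, 180],
# times are seconds throughout.

#' Convert two-axis accelerometer samples into an angle trace
#'
#' The segment (crank or thigh) angle is obtained from the ratio of the two
#' acceleration components. A full-quadrant (two-argument) arctangent of
#' `(ax, ay)` is used so the angle covers the whole circle, in degrees mapped
#' into `(-180, 180]`: `theta = atan2(ax, ay) * 180 / pi`.
#'
#' @param samples A data frame (or coercible object) with numeric columns
#'   `t` (seconds, strictly increasing), `ax` and `ay` (acceleration in g
#'   along the two sensor axes).
#' @return An `angle_trace`: a data frame with columns `t` and `theta`
#'   (degrees in `(-180, 180]`).
#' @examples
#' accel_to_angle(data.frame(t = 0:2, ax = c(0, 1, 0), ay = c(1, 1, -1)))
#' @seealso [segment_cycles()], [unwrap_angle()]
#' @export
accel_to_angle <- function(samples) {
  samples <- as.data.frame(samples)
  if (!all(c("t", "ax", "ay") %in% names(samples)))
    stop("`samples` must have columns t, ax, ay")
  t <- as.numeric(samples$t)
  ax <- as.numeric(samples$ax)
  ay <- as.numeric(samples$ay)
  if (anyNA(t) || any(!is.finite(ax)) || any(!is.finite(ay)))
    stop("non-finite values in accelerometer samples")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  bad <- which(ax == 0 & ay == 0)
  if (length(bad))
    stop(sprintf(
      "degenerate accelerometer sample (ax = ay = 0) at index %d: angle undefined",
      bad[1L]
    ))
  theta <- atan2(ax, ay) * 180 / pi
  theta[theta <= -180] <- theta[theta <= -180] + 360
  structure(data.frame(t = t, theta = theta),
            class = c("angle_trace", "data.frame"))
}

#' Wrap angles into the half-open interval (-180, 180] degrees
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Numeric vector of the same length with every value in
#'   `(-180, 180]`.
#' @export
wrap_angle <- function(theta) {
  w <- theta %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Unwrap a wrapped angle trace into a continuous angle
#'
#' Removes the +/-180 degree discontinuities so that successive differences
#' are below 180 degrees in magnitude. Needed to count revolutions across the
#' wrap. Wrapping the result back with [wrap_angle()] reproduces the input.
#'
#' @param trace An `angle_trace` (see [accel_to_angle()]) or a numeric vector
#'   of wrapped angles in degrees.
#' @return Numeric vector of continuous (unbounded) angles in degrees.
#' @export
unwrap_angle <- function(trace) {
  theta <- if (is.data.frame(trace)) trace$theta else as.numeric(trace)
  n <- length(theta)
  if (n == 0L) return(numeric(0))
  d <- diff(theta)
  d <- d - 360 * round(d / 360)
  d[d == -180] <- 180
  cumsum(c(theta[1L], d))
}

#' Segment an angle trace into movement cycles
#'
#' A cycle boundary is placed at each upward crossing of `reference_angle`
#' in the unwrapped trace. Crossings are detected as first passages through
#' the levels `reference_angle + k * 360`, which makes the count robust to
#' noise-induced re-crossings of a single level: each revolution contributes
#' exactly one boundary. Boundary times are refined by linear interpolation
#' between the bracketing samples.
#'
#' @param trace An `angle_trace` (columns `t`, `theta`).
#' @param reference_angle Crossing reference in degrees (default 0).
#' @return A `cycle_segmentation`: list with `boundaries` (sample indices of
#'   the first sample at/after each crossing), `times` (interpolated crossing
#'   times, seconds), `n_cycles` (`length(boundaries) - 1`, 0 if fewer than
#'   two crossings) and `periods` (seconds per cycle).
#' @examples
#' imu <- simulate_motion_imu(motion_sim_config("pedaling", 2.5, 10))
#' segment_cycles(accel_to_angle(imu))
#' @export
segment_cycles <- function(trace, reference_angle = 0) {
  stopifnot(is.data.frame(trace), all(c("t", "theta") %in% names(trace)))
  t <- trace$t
  u <- unwrap_angle(trace)
  n <- length(u)
  eps <- 1e-9
  empty <- structure(
    list(boundaries = integer(0), times = numeric(0),
         n_cycles = 0L, periods = numeric(0),
         reference_angle = reference_angle),
    class = "cycle_segmentation"
  )
  if (n < 2L) return(empty)
  k0 <- ceiling((u[1L] - reference_angle) / 360 - eps)
  k1 <- floor((max(u) - reference_angle) / 360 + eps)
  if (k1 < k0) return(empty)
  idx <- integer(0)
  times <- numeric(0)
  for (k in k0:k1) {
    lev <- reference_angle + 360 * k
    if (lev <= u[1L] + eps * max(1, abs(lev))) {
      # trace starts exactly on the level: boundary at the first sample
      if (abs(u[1L] - lev) <= 1e-6) {
        idx <- c(idx, 1L)
        times <- c(times, t[1L])
      }
      next
    }
    i <- which(u >= lev)[1L]
    if (is.na(i) || i == 1L) next
    frac <- (lev - u[i - 1L]) / (u[i] - u[i - 1L])
    idx <- c(idx, i)
    times <- c(times, t[i - 1L] + frac * (t[i] - t[i - 1L]))
  }
  if (length(idx) < 2L) return(empty)
  structure(
    list(boundaries = idx, times = times,
         n_cycles = length(idx) - 1L, periods = diff(times),
         reference_angle = reference_angle),
    class = "cycle_segmentation"
  )
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycle(s)", x$n_cycles))
  if (x$n_cycles > 0)
    cat(sprintf(", mean period %.3f s (%.3f Hz)",
                mean(x$periods), 1 / mean(x$periods)))
  cat("\n")
  invisible(x)
}

#' Estimate the movement frequency (cadence) of a segmentation
#'
#' Returns `1 / mean(periods)` in Hz. Per-cycle instantaneous frequencies
#' (`1 / periods`) are attached as the attribute `"cycle_frequencies"`.
#'
#' @param seg A `cycle_segmentation` from [segment_cycles()].
#' @return Movement frequency in Hz (numeric scalar) with attribute
#'   `cycle_frequencies`.
#' @export
estimate_frequency <- function(seg) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  if (seg$n_cycles < 1L)
    stop("movement frequency is undefined for an empty segmentation")
  f <- 1 / mean(seg$periods)
  attr(f, "cycle_frequencies") <- 1 / seg$periods
  f
}

#' Resample one cycle onto an evenly spaced 0-100% grid
#'
#' Linear interpolation of `values` (assumed uniformly sampled over one
#' movement cycle) onto `n_points` evenly spaced points covering 0-100% of
#' the cycle. Endpoints are preserved exactly. With the default of 101
#' points, index `i` corresponds to cycle percentage `i - 1`.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_points Number of output points (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
resample_cycle <- function(values, n_points = 101L) {
  if (length(values) < 2L)
    stop("need at least 2 samples to resample a cycle")
  if (n_points < 2L)
    stop("n_points must be at least 2")
  stats::approx(seq(0, 1, length.out = length(values)), values,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Resample an IMU trace onto a uniform sampling grid
#'
#' Linearly interpolates irregularly timestamped accelerometer samples onto
#' the nominal rate prior to segmentation or control.
#'
#' @param samples Data frame with columns `t`, `ax`, `ay`.
#' @param rate Target sampling rate in Hz (default 20, the nominal IMU rate).
#' @return Data frame with columns `t`, `ax`, `ay` on a uniform grid spanning
#'   the original time range.
#' @export
resample_imu <- function(samples, rate = 20) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("t", "ax", "ay") %in% names(samples)), rate > 0)
  if (nrow(samples) < 2L) stop("need at least 2 samples to resample")
  tt <- seq(samples$t[1L], samples$t[nrow(samples)], by = 1 / rate)
  data.frame(
    t = tt,
    ax = stats::approx(samples$t, samples$ax, xout = tt)$y,
    ay = stats::approx(samples$t, samples$ay, xout = tt)$y
  )
}
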