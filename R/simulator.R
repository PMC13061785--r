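# Synthetic signal generators: cyclic two-axis accelerometer traces for
# pedaling/gait, and multichannel EEG with a 1/f background plus band-limited
# mu and beta components whose power is modulated during movement. Used to
# exercise the controller and the spectral pipeline end to end without
# hardware, with analytic ground truth.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Motion simulator configuration
#'
#' @param mode `"pedaling"` (uniform rotation) or `"gait"` (piecewise
#'   angular velocity: 60% of the period for a stance half-circle, 40% for
#'   the swing half-circle, keeping the same cycle period).
#' @param cycle_period Cycle period T in seconds (> 0).
#' @param duration Trace duration in seconds (> 0); samples cover
#'   `[0, duration]` inclusive.
#' @param imu_rate Sampling rate in Hz (default 20, the nominal sensor rate).
#' @param noise_sigma Standard deviation of the additive Gaussian
#'   accelerometer noise, in g (default 0).
#' @param seed Integer seed (or `NULL` to draw from the current RNG stream).
#' @param phase_deg Starting angle in degrees (default 0).
#' @return A `motion_sim_config` object.
#' @export
motion_sim_config <- function(mode = c("pedaling", "gait"), cycle_period,
                              duration, imu_rate = 20, noise_sigma = 0,
                              seed = NULL, phase_deg = 0) {
  mode <- match.arg(mode)
  stopifnot(cycle_period > 0, duration > 0, imu_rate > 0, noise_sigma >= 0)
  structure(
    list(mode = mode, cycle_period = cycle_period, duration = duration,
         imu_rate = imu_rate, noise_sigma = noise_sigma, seed = seed,
         phase_deg = phase_deg),
    class = "motion_sim_config"
  )
}

# Cumulative fraction of the circle covered at within-cycle position
# s in [0, 1). Gait: slow stance (60% of time, half the circle), fast swing.
cycle_fraction <- function(s, mode) {
  if (mode == "pedaling") return(s)
  ifelse(s < 0.6, 0.5 * s / 0.6, 0.5 + 0.5 * (s - 0.6) / 0.4)
}

#' Simulate a two-axis accelerometer trace for cyclic movement
#'
#' The underlying continuous angle advances 360 degrees per cycle period;
#' the accelerometer axes are `ax = sin(theta) + e`, `ay = cos(theta) + e`
#' with independent Gaussian noise, so [accel_to_angle()] recovers the
#' rotating angle. The true angle is attached as attribute `"true_theta"`.
#'
#' @param config A [motion_sim_config()].
#' @return Data frame with columns `t`, `ax`, `ay` (class `imu_trace`).
#' @examples
#' imu <- simulate_motion_imu(
#'   motion_sim_config("pedaling", cycle_period = 2.5, duration = 30))
#' estimate_frequency(segment_cycles(accel_to_angle(imu)))
#' @export
simulate_motion_imu <- function(config) {
  stopifnot(inherits(config, "motion_sim_config"))
  t <- seq(0, config$duration, by = 1 / config$imu_rate)
  cyc <- t / config$cycle_period
  k <- floor(cyc)
  frac <- cycle_fraction(cyc - k, config$mode)
  theta <- config$phase_deg + 360 * (k + frac)
  rad <- theta * pi / 180
  n <- length(t)
  noise <- with_seed(config$seed, {
    matrix(stats::rnorm(2L * n, sd = config$noise_sigma), ncol = 2L)
  })
  out <- data.frame(t = t,
                    ax = sin(rad) + noise[, 1L],
                    ay = cos(rad) + noise[, 2L])
  class(out) <- c("imu_trace", "data.frame")
  attr(out, "true_theta") <- theta
  attr(out, "config") <- config
  out
}

#' Standard 16-electrode 10-20 montage with flat-map coordinates
#'
#' The montage used for acquisition: Fp1, Fp2, F3, F4, FC1, FC2, C3, Cz,
#' C4, CP1, CP2, P3, P4, P7, P8 and Pz. Coordinates are an azimuthal
#' (top-view) projection in head radii, x to the right, y to the front;
#' only relative scalp distances are used by the simulator.
#'
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
eeg_montage_1020 <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "F3", "F4", "FC1", "FC2", "C3", "Cz",
              "C4", "CP1", "CP2", "P3", "P4", "P7", "P8", "Pz"),
    x = c(-0.31, 0.31, -0.45, 0.45, -0.28, 0.28, -0.55, 0,
          0.55, -0.28, 0.28, -0.45, 0.45, -0.81, 0.81, 0),
    y = c(0.95, 0.95, 0.55, 0.55, 0.28, 0.28, 0, 0,
          0, -0.28, -0.28, -0.55, -0.55, -0.59, -0.59, -0.55),
    stringsAsFactors = FALSE
  )
}

#' EEG simulator configuration
#'
#' Each channel is the sum of a 1/f^a background and two band-limited
#' Gaussian components: a mu component spanning `mu_band` and a beta
#' component spanning `beta_band`. Component amplitudes fall off
#' exponentially with scalp distance from Cz (`amp_falloff`), making the
#' sensorimotor rhythms Cz-focal. During movement (between the first and
#' last cycle boundary) the mu power at Cz changes by `erd_db_at_cz` dB
#' relative to rest (negative = desynchronization), the beta power by
#' `beta_erd_db_at_cz`; the dB modulation itself decays with distance from
#' Cz with length scale `erd_falloff`. Optionally a low-pass-filtered
#' replica of the commanded stimulation pulse train is mixed into all
#' channels while any channel is commanded on (`artifact_params`,
#' `artifact_amp_uv`).
#'
#' @param montage Electrode data frame (default [eeg_montage_1020()]); must
#'   contain `label`, `x`, `y`.
#' @param eeg_rate Sampling rate in Hz (default 512).
#' @param background_exponent Spectral slope a of the 1/f^a background
#'   (default 1).
#' @param background_amp_uv Background standard deviation in uV (default 2).
#' @param mu_band,beta_band Band edges in Hz (defaults 8-13 and 20-30).
#' @param mu_amp_cz_uv,beta_amp_cz_uv Component standard deviations at Cz at
#'   rest, in uV (defaults 20 and 10).
#' @param amp_falloff Length scale (head radii) of the component-amplitude
#'   falloff with distance from Cz (default 0.5).
#' @param erd_falloff Length scale (head radii) of the movement-modulation
#'   falloff (default 0.3).
#' @param erd_db_at_cz Movement-versus-rest change of mu power at Cz in dB
#'   (default 0).
#' @param beta_erd_db_at_cz Same for the beta component (default 0).
#' @param artifact_params Optional [stim_params()] describing the
#'   stimulation waveform bled into the EEG; `NULL` disables the artifact.
#' @param artifact_amp_uv Artifact amplitude scale in uV (default 0).
#' @param seed Integer seed (or `NULL`).
#' @return An `eeg_sim_config` object.
#' @export
eeg_sim_config <- function(montage = eeg_montage_1020(), eeg_rate = 512,
                           background_exponent = 1, background_amp_uv = 2,
                           mu_band = c(8, 13), beta_band = c(20, 30),
                           mu_amp_cz_uv = 20, beta_amp_cz_uv = 10,
                           amp_falloff = 0.5, erd_falloff = 0.3,
                           erd_db_at_cz = 0, beta_erd_db_at_cz = 0,
                           artifact_params = NULL, artifact_amp_uv = 0,
                           seed = NULL) {
  stopifnot(is.data.frame(montage),
            all(c("label", "x", "y") %in% names(montage)),
            !anyDuplicated(montage$label),
            eeg_rate > 0, background_amp_uv >= 0,
            length(mu_band) == 2L, length(beta_band) == 2L,
            mu_amp_cz_uv >= 0, beta_amp_cz_uv >= 0,
            amp_falloff > 0, erd_falloff > 0, artifact_amp_uv >= 0)
  if (!is.null(artifact_params))
    stopifnot(inherits(artifact_params, "stim_params"))
  structure(
    list(montage = montage, eeg_rate = eeg_rate,
         background_exponent = background_exponent,
         background_amp_uv = background_amp_uv,
         mu_band = mu_band, beta_band = beta_band,
         mu_amp_cz_uv = mu_amp_cz_uv, beta_amp_cz_uv = beta_amp_cz_uv,
         amp_falloff = amp_falloff, erd_falloff = erd_falloff,
         erd_db_at_cz = erd_db_at_cz,
         beta_erd_db_at_cz = beta_erd_db_at_cz,
         artifact_params = artifact_params,
         artifact_amp_uv = artifact_amp_uv, seed = seed),
    class = "eeg_sim_config"
  )
}

# Gaussian noise whose spectrum is flat inside [lo, hi] Hz and zero
# outside, scaled to standard deviation `sd_target`.
band_limited_noise <- function(n, rate, lo, hi, sd_target) {
  if (sd_target == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * rate / n
  fsym <- pmin(f, rate - f)
  X[fsym < lo | fsym > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y * sd_target / stats::sd(y)
}

# 1/f^a background via spectral shaping of white noise; the shaping weight
# is clamped below 0.5 Hz to keep the variance finite.
one_over_f_noise <- function(n, rate, exponent, sd_target) {
  if (sd_target == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * rate / n
  fsym <- pmax(pmin(f, rate - f), 0.5)
  w <- 1 / fsym^(exponent / 2)
  w[1L] <- 0 # no DC
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  y * sd_target / stats::sd(y)
}

scalp_distance_from_cz <- function(montage) {
  cz <- montage[montage$label == "Cz", , drop = FALSE]
  if (nrow(cz) != 1L) stop("montage must contain a single Cz electrode")
  sqrt((montage$x - cz$x)^2 + (montage$y - cz$y)^2)
}

# Low-pass-filtered stimulation waveform sampled on the EEG time grid,
# nonzero only while a channel is commanded on.
fes_artifact_wave <- function(config, t_eeg, command_log) {
  params <- config$artifact_params
  duration <- t_eeg[length(t_eeg)] + 1 / config$eeg_rate
  train <- generate_pulse_train(params, duration)
  cutoff <- min(200, 0.45 * config$eeg_rate)
  bf <- signal::butter(4, cutoff / (params$sample_rate_hz / 2), type = "low")
  smooth <- signal::filtfilt(bf, train$amplitude)
  idx <- pmin(length(smooth), floor(t_eeg * params$sample_rate_hz) + 1L)
  wave <- smooth[idx]
  on_rows <- nzchar(command_log$active_channels)
  if (!any(on_rows)) return(numeric(length(t_eeg)))
  pos <- findInterval(t_eeg, command_log$t)
  on <- pos >= 1L & on_rows[pmax(pos, 1L)]
  wave * as.numeric(on)
}

simulate_eeg_internal <- function(config, cycle_boundaries, duration,
                                  command_log = NULL, modulate = TRUE) {
  rate <- config$eeg_rate
  n <- floor(duration * rate)
  if (n < 2L) stop("duration too short for the configured EEG rate")
  t <- (seq_len(n) - 1L) / rate
  m <- config$montage
  nch <- nrow(m)
  d <- scalp_distance_from_cz(m)
  a_mu <- config$mu_amp_cz_uv * exp(-d / config$amp_falloff)
  a_beta <- config$beta_amp_cz_uv * exp(-d / config$amp_falloff)
  g_mu <- 10^((config$erd_db_at_cz * exp(-d / config$erd_falloff)) / 20)
  g_beta <- 10^((config$beta_erd_db_at_cz *
                   exp(-d / config$erd_falloff)) / 20)
  moving <- rep(FALSE, n)
  if (modulate && length(cycle_boundaries) >= 2L)
    moving <- t >= cycle_boundaries[1L] &
      t <= cycle_boundaries[length(cycle_boundaries)]
  data <- with_seed(config$seed, {
    out <- matrix(0, nrow = nch, ncol = n)
    for (ch in seq_len(nch)) {
      bg <- one_over_f_noise(n, rate, config$background_exponent,
                             config$background_amp_uv)
      mu <- band_limited_noise(n, rate, config$mu_band[1L],
                               config$mu_band[2L], a_mu[ch])
      be <- band_limited_noise(n, rate, config$beta_band[1L],
                               config$beta_band[2L], a_beta[ch])
      env_mu <- ifelse(moving, g_mu[ch], 1)
      env_be <- ifelse(moving, g_beta[ch], 1)
      out[ch, ] <- bg + mu * env_mu + be * env_be
    }
    out
  })
  if (!is.null(config$artifact_params) && config$artifact_amp_uv > 0 &&
      !is.null(command_log) && nrow(command_log) > 0L)
    data <- data + matrix(
      config$artifact_amp_uv * fes_artifact_wave(config, t, command_log),
      nrow = nch, ncol = n, byrow = TRUE)
  eeg_recording(data, rate, m$label)
}

#' Simulate multichannel EEG during a movement session
#'
#' See [eeg_sim_config()] for the generative model. Movement modulation is
#' applied between the first and last cycle boundary; the rest of the
#' recording carries resting-state power.
#'
#' @param config An [eeg_sim_config()].
#' @param cycle_boundaries Numeric vector of cycle boundary times (seconds),
#'   e.g. `segment_cycles(...)$times`; all must lie within `duration`.
#' @param duration Recording duration in seconds.
#' @param command_log Optional `command_log` (from [run_controller()]) used
#'   to gate the stimulation artifact.
#' @return An `eeg_recording` (see [eeg_recording()]).
#' @export
simulate_eeg <- function(config, cycle_boundaries, duration,
                         command_log = NULL) {
  stopifnot(inherits(config, "eeg_sim_config"))
  if (length(cycle_boundaries) &&
      (min(cycle_boundaries) < 0 || max(cycle_boundaries) > duration))
    stop("cycle boundaries must lie within the recording duration")
  simulate_eeg_internal(config, cycle_boundaries, duration, command_log,
                        modulate = TRUE)
}

#' Simulate a resting-state EEG baseline
#'
#' Background plus band components at rest power: no movement modulation
#' and no stimulation artifact.
#'
#' @param config An [eeg_sim_config()].
#' @param duration Recording duration in seconds (> 0).
#' @return An `eeg_recording`.
#' @export
simulate_rest <- function(config, duration) {
  stopifnot(inherits(config, "eeg_sim_config"), duration > 0)
  simulate_eeg_internal(config, numeric(0), duration, NULL,
                        modulate = FALSE)
}

#' Run a complete closed-loop session without hardware
#'
#' Simulates the IMU trace, streams it through the phase controller,
#' segments the angle trace into cycles, and generates EEG conditioned on
#' the cycle boundaries and the command log. All streams share the time
#' origin t = 0.
#'
#' @param motion A [motion_sim_config()].
#' @param task A [task_config()].
#' @param eeg An [eeg_sim_config()], or `NULL` to skip EEG generation.
#' @param emergency_stop_at,reset_at Optional times (s) forwarded to
#'   [run_controller()] to exercise the safety latch.
#' @param reference_angle Cycle-segmentation reference in degrees
#'   (default 0).
#' @return A `session_record`: list with `imu`, `angle`, `commands`,
#'   `segmentation`, `events` (boundary times) and `eeg` (or `NULL`).
#' @export
run_closed_loop_session <- function(motion, task, eeg = NULL,
                                    emergency_stop_at = NULL,
                                    reset_at = NULL, reference_angle = 0) {
  stopifnot(inherits(motion, "motion_sim_config"),
            inherits(task, "task_config"))
  imu <- simulate_motion_imu(motion)
  angle <- accel_to_angle(imu)
  commands <- run_controller(imu, task, emergency_stop_at = emergency_stop_at,
                             reset_at = reset_at)
  seg <- segment_cycles(angle, reference_angle)
  rec <- NULL
  if (!is.null(eeg)) {
    stopifnot(inherits(eeg, "eeg_sim_config"))
    rec <- simulate_eeg(eeg, seg$times, motion$duration, commands)
  }
  structure(
    list(imu = imu, angle = angle, commands = commands, segmentation = seg,
         events = seg$times, eeg = rec,
         configs = list(motion = motion, task = task, eeg = eeg)),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> %.1f s, %d IMU samples, %d cycle(s), %d command(s)%s\n",
    max(x$imu$t), nrow(x$imu), x$segmentation$n_cycles, nrow(x$commands),
    if (is.null(x$eeg)) "" else sprintf(", EEG %d ch x %d samples",
                                        nrow(x$eeg$data), ncol(x$eeg$data))))
  invisible(x)
}
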