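# Stimulation parameters and sampled biphasic pulse trains. Amplitudes are
# normalized to the channel maximum (intensity percent / 100); absolute
# currents are a hardware property and out of scope.

#' Stimulation parameter set
#'
#' Validates and bundles the per-channel stimulation settings: pulse
#' repetition frequency (Hz), per-phase pulse width (microseconds) and
#' intensity as a percentage of the channel maximum. The protocol defaults
#' are 35 Hz, 300 us and 75%.
#'
#' @param frequency_hz Pulse repetition rate in Hz (> 0).
#' @param pulse_width_us Width of each pulse phase in microseconds (> 0).
#'   A biphasic pulse occupies `2 * pulse_width_us`, which must fit inside
#'   one repetition period.
#' @param intensity_pct Intensity, percent of channel maximum (0-100).
#' @param sample_rate_hz Sampling rate used when synthesizing the waveform
#'   (default 1e5 Hz so a 300 us phase spans 30 samples).
#' @return A `stim_params` object (list).
#' @export
stim_params <- function(frequency_hz = 35, pulse_width_us = 300,
                        intensity_pct = 75, sample_rate_hz = 1e5) {
  if (!is.finite(frequency_hz) || frequency_hz <= 0)
    stop("frequency_hz must be positive")
  if (!is.finite(pulse_width_us) || pulse_width_us <= 0)
    stop("pulse_width_us must be positive")
  if (2 * pulse_width_us * 1e-6 >= 1 / frequency_hz)
    stop("biphasic pulse (2 x pulse_width) must fit within one period: ",
         "reduce pulse_width_us or frequency_hz")
  if (!is.finite(intensity_pct) || intensity_pct < 0 || intensity_pct > 100)
    stop("intensity_pct must lie in [0, 100]")
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  structure(
    list(frequency_hz = frequency_hz,
         pulse_width_us = pulse_width_us,
         intensity_pct = intensity_pct,
         sample_rate_hz = sample_rate_hz),
    class = "stim_params"
  )
}

#' @export
print.stim_params <- function(x, ...) {
  cat(sprintf("<stim_params> %g Hz, %g us, %g%% of max (synthesis at %g Hz)\n",
              x$frequency_hz, x$pulse_width_us, x$intensity_pct,
              x$sample_rate_hz))
  invisible(x)
}

#' Synthesize a sampled biphasic pulse train
#'
#' Generates symmetric charge-balanced biphasic rectangular pulses: a
#' positive phase of `pulse_width_us`, immediately followed by a negative
#' phase of the same width, one pulse per `1 / frequency_hz`, amplitude
#' `+/- intensity_pct / 100`. Pulses that would not fit completely inside
#' `duration` are dropped so the train stays charge balanced.
#'
#' @param params A [stim_params()] object.
#' @param duration Train duration in seconds (> 0).
#' @return A `pulse_train`: list with `t` (seconds), `amplitude` (normalized,
#'   in `[-1, 1]`) and `params`.
#' @examples
#' train <- generate_pulse_train(stim_params(35, 300, 75), duration = 1)
#' measure_pulse_rate(train)
#' @export
generate_pulse_train <- function(params, duration) {
  stopifnot(inherits(params, "stim_params"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  fs <- params$sample_rate_hz
  pw <- params$pulse_width_us * 1e-6
  if (fs < 20 / pw)
    stop(sprintf(
      "sample_rate_hz too low: need >= 20 samples per pulse phase (>= %g Hz)",
      20 / pw))
  n <- round(duration * fs)
  w <- round(pw * fs)
  amp <- params$intensity_pct / 100
  a <- numeric(n)
  k <- 0L
  repeat {
    s0 <- floor(k / params$frequency_hz * fs) # 0-based onset sample
    if (s0 + 2L * w > n || k / params$frequency_hz >= duration) break
    a[(s0 + 1L):(s0 + w)] <- amp
    a[(s0 + w + 1L):(s0 + 2L * w)] <- -amp
    k <- k + 1L
  }
  structure(list(t = (seq_len(n) - 1L) / fs, amplitude = a, params = params),
            class = "pulse_train")
}

pulse_onsets <- function(train) {
  a <- train$amplitude
  n <- length(a)
  on <- which(a[-1L] > 0 & a[-n] <= 0) + 1L
  if (n >= 1L && a[1L] > 0) on <- c(1L, on)
  on
}

#' Measure the pulse repetition rate of a train
#'
#' Counts positive-phase onsets; the rate is `(count - 1)` divided by the
#' time between the first and last onset.
#'
#' @param train A `pulse_train` from [generate_pulse_train()].
#' @return Repetition rate in Hz.
#' @export
measure_pulse_rate <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  on <- pulse_onsets(train)
  if (length(on) < 2L)
    stop("need at least 2 pulses to measure a repetition rate")
  (length(on) - 1) / (train$t[on[length(on)]] - train$t[on[1L]])
}

#' Measure the mean positive-phase pulse width of a train
#'
#' @param train A `pulse_train` from [generate_pulse_train()].
#' @return Mean positive-phase duration in microseconds.
#' @export
measure_pulse_width <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  r <- rle(train$amplitude > 0)
  lens <- r$lengths[r$values]
  if (length(lens) == 0L) stop("train contains no pulses")
  dt <- 1 / train$params$sample_rate_hz
  mean(lens) * dt * 1e6
}

#' Build a gradual intensity ramp-up schedule
#'
#' Stimulation is ramped up before a session; this returns the parameter
#' sequence from `step_pct` up to `target_pct` in increments of `step_pct`,
#' with the final element clamped to exactly `target_pct`.
#'
#' @param params Base [stim_params()] (its intensity is replaced).
#' @param target_pct Final intensity, percent (0-100).
#' @param step_pct Increment per step, percent (> 0).
#' @return A list of `stim_params`, one per step; empty when `target_pct`
#'   is 0.
#' @export
ramp_intensity <- function(params, target_pct, step_pct) {
  stopifnot(inherits(params, "stim_params"))
  if (!is.finite(target_pct) || target_pct < 0 || target_pct > 100)
    stop("target_pct must lie in [0, 100]")
  if (!is.finite(step_pct) || step_pct <= 0) stop("step_pct must be positive")
  if (target_pct == 0) return(list())
  v <- seq(step_pct, target_pct, by = step_pct)
  if (length(v) == 0L || v[length(v)] < target_pct) v <- c(v, target_pct)
  lapply(v, function(i)
    stim_params(params$frequency_hz, params$pulse_width_us, i,
                params$sample_rate_hz))
}

#' Write a pulse train to CSV
#'
#' @param train A `pulse_train`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pulse_train_csv <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  utils::write.csv(data.frame(t = train$t, amplitude = train$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}
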