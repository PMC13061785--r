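# Finite-state phase controller: classify the current segment angle into a
# movement phase and emit per-channel stimulation commands, with software
# safety interlocks (latched emergency stop, command-rate ceiling, dwell
# debouncing at phase boundaries).

#' Define a movement phase
#'
#' A named phase is an inclusive angle range plus the stimulation channels
#' (and muscle labels) active while the angle lies inside it. A range that
#' straddles the +/-180 degree wrap is expressed as two definitions sharing
#' one name.
#'
#' @param name Phase label.
#' @param theta_min,theta_max Inclusive angle range in degrees,
#'   `-180 <= theta_min <= theta_max <= 180`.
#' @param channels Integer vector of stimulation channel ids (1-8), unique,
#'   nonempty.
#' @param muscles Character vector of muscle labels (recycled/free-form
#'   description of what each channel stimulates).
#' @return A `phase_definition` object.
#' @export
phase_definition <- function(name, theta_min, theta_max, channels,
                             muscles = character(0)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("phase name must be a nonempty string")
  if (theta_min < -180 || theta_max > 180 || theta_min > theta_max)
    stop(sprintf("phase '%s': need -180 <= theta_min <= theta_max <= 180",
                 name))
  channels <- as.integer(channels)
  if (length(channels) == 0L || anyNA(channels) ||
      any(channels < 1L | channels > 8L))
    stop(sprintf("phase '%s': channels must be a nonempty subset of 1-8",
                 name))
  if (anyDuplicated(channels))
    stop(sprintf("phase '%s': duplicate channel ids", name))
  structure(
    list(name = name, theta_min = theta_min, theta_max = theta_max,
         channels = channels, muscles = as.character(muscles)),
    class = "phase_definition"
  )
}

#' Assemble and validate a task configuration
#'
#' A pedaling task has exactly 2 named phases, a gait task exactly 4; phase
#' angle ranges must be pairwise disjoint. Overlaps are a configuration
#' error caught here (at load time), never at classification time.
#'
#' @param mode `"pedaling"` or `"gait"`.
#' @param phases List of [phase_definition()]s, in cycle order.
#' @param stim A [stim_params()] object applied to all configured channels,
#'   or a named list of `stim_params` keyed by channel id.
#' @param min_dwell_s Minimum time (seconds) the controller stays in a phase
#'   before honouring a transition (debounce, default 0.1).
#' @param max_command_rate_hz Ceiling on the granted command/stimulation
#'   update rate (default 50), enforced by [enforce_frequency_lock()].
#' @return A `task_config` object.
#' @seealso [build_pedaling_config()], [build_gait_config()]
#' @export
task_config <- function(mode, phases, stim = stim_params(),
                        min_dwell_s = 0.1, max_command_rate_hz = 50) {
  mode <- match.arg(mode, c("pedaling", "gait"))
  if (!is.list(phases) || !all(vapply(phases, inherits, TRUE,
                                      "phase_definition")))
    stop("phases must be a list of phase_definition objects")
  nm <- unique(vapply(phases, `[[`, "", "name"))
  want <- if (mode == "pedaling") 2L else 4L
  if (length(nm) != want)
    stop(sprintf("%s mode requires exactly %d named phases, got %d",
                 mode, want, length(nm)))
  # pairwise disjoint inclusive ranges (also across same-name definitions)
  if (length(phases) > 1L) {
    lo <- vapply(phases, `[[`, 0, "theta_min")
    hi <- vapply(phases, `[[`, 0, "theta_max")
    o <- order(lo)
    if (any(hi[o][-length(o)] >= lo[o][-1L]))
      stop("phase angle ranges must be pairwise disjoint")
  }
  if (inherits(stim, "stim_params")) {
    ch <- sort(unique(unlist(lapply(phases, `[[`, "channels"))))
    stim <- stats::setNames(rep(list(stim), length(ch)), as.character(ch))
  }
  if (!all(vapply(stim, inherits, TRUE, "stim_params")))
    stop("stim must be stim_params or a list of stim_params per channel")
  if (!is.finite(min_dwell_s) || min_dwell_s < 0)
    stop("min_dwell_s must be >= 0")
  if (!is.finite(max_command_rate_hz) || max_command_rate_hz <= 0)
    stop("max_command_rate_hz must be positive")
  structure(
    list(mode = mode, phases = phases, stim = stim,
         min_dwell_s = min_dwell_s,
         max_command_rate_hz = max_command_rate_hz),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("<task_config> mode=%s, %d phase definition(s)\n",
              x$mode, length(x$phases)))
  for (p in x$phases)
    cat(sprintf("  %-16s [%7.1f, %7.1f] deg -> channels {%s}\n",
                p$name, p$theta_min, p$theta_max,
                paste(p$channels, collapse = ",")))
  invisible(x)
}

phase_channels <- function(config, name) {
  if (is.na(name)) return(integer(0))
  for (p in config$phases) if (p$name == name) return(p$channels)
  integer(0)
}

#' Classify an angle into a movement phase
#'
#' @param theta Angle in degrees, in `(-180, 180]`.
#' @param config A [task_config()].
#' @return The matching phase label, or `NA_character_` when the angle falls
#'   outside every configured range (no stimulation).
#' @export
classify_phase <- function(theta, config) {
  stopifnot(inherits(config, "task_config"), is.finite(theta))
  for (p in config$phases)
    if (theta >= p$theta_min && theta <= p$theta_max) return(p$name)
  NA_character_
}

#' Create a fresh controller state
#'
#' @return A `controller_state`: no current phase, emergency stop cleared.
#' @export
new_controller_state <- function() {
  structure(
    list(current_phase = NA_character_, phase_entry_time = -Inf,
         emergency_stopped = FALSE, last_command_time = -Inf),
    class = "controller_state"
  )
}

#' Latch the emergency stop
#'
#' Once triggered, every subsequent command has all channels off until an
#' explicit [reset_emergency_stop()]. Idempotent.
#'
#' @param state A `controller_state`.
#' @return The stopped state.
#' @export
trigger_emergency_stop <- function(state) {
  stopifnot(inherits(state, "controller_state"))
  state$emergency_stopped <- TRUE
  state
}

#' Clear a latched emergency stop
#'
#' @param state A `controller_state`.
#' @return The state with the latch cleared; normal operation resumes on the
#'   next sample.
#' @export
reset_emergency_stop <- function(state) {
  stopifnot(inherits(state, "controller_state"))
  state$emergency_stopped <- FALSE
  state
}

#' Clamp a requested command/stimulation rate to the configured ceiling
#'
#' Software analogue of the firmware maximum-frequency lock: the granted
#' rate never exceeds `max_command_rate_hz`.
#'
#' @param requested_rate_hz Requested rate in Hz (>= 0).
#' @param config A [task_config()].
#' @return The granted rate, `min(requested, ceiling)`.
#' @export
enforce_frequency_lock <- function(requested_rate_hz, config) {
  stopifnot(inherits(config, "task_config"))
  if (!is.finite(requested_rate_hz) || requested_rate_hz < 0)
    stop("requested rate must be >= 0")
  min(requested_rate_hz, config$max_command_rate_hz)
}

stim_of_channels <- function(config, channels) {
  if (length(channels) == 0L) return(stim_params(intensity_pct = 0))
  config$stim[[as.character(channels[1L])]]
}

#' Advance the controller by one IMU sample
#'
#' Computes the angle from the sample, classifies it, applies the dwell
#' debounce (a transition is honoured only after `min_dwell_s` in the
#' current phase) and emits the stimulation command for the resulting phase.
#' When the emergency stop is latched the command is all-off regardless of
#' the angle. Malformed samples (non-finite, or `ax = ay = 0`) are skipped
#' with a warning and yield a `NULL` command.
#'
#' @param state A `controller_state`.
#' @param sample A list/row with `t`, `ax`, `ay`.
#' @param config A [task_config()].
#' @return List with elements `state` (updated) and `command` (a
#'   `stim_command`: `t`, `phase`, `active_channels`, `params`; or `NULL`
#'   for a skipped sample).
#' @export
step_controller <- function(state, sample, config) {
  stopifnot(inherits(state, "controller_state"),
            inherits(config, "task_config"))
  t <- sample$t; ax <- sample$ax; ay <- sample$ay
  if (!is.finite(t) || !is.finite(ax) || !is.finite(ay) ||
      (ax == 0 && ay == 0)) {
    warning(sprintf("skipping malformed IMU sample at t=%s",
                    format(sample$t)))
    return(list(state = state, command = NULL))
  }
  if (state$emergency_stopped) {
    state$last_command_time <- t
    cmd <- structure(
      list(t = t, phase = NA_character_, active_channels = integer(0),
           params = stim_of_channels(config, integer(0))),
      class = "stim_command"
    )
    return(list(state = state, command = cmd))
  }
  theta <- atan2(ax, ay) * 180 / pi
  if (theta <= -180) theta <- theta + 360
  cand <- classify_phase(theta, config)
  cur <- state$current_phase
  same <- (is.na(cand) && is.na(cur)) ||
    (!is.na(cand) && !is.na(cur) && cand == cur)
  if (!same && (t - state$phase_entry_time) >= config$min_dwell_s) {
    state$current_phase <- cand
    state$phase_entry_time <- t
  }
  channels <- phase_channels(config, state$current_phase)
  state$last_command_time <- t
  cmd <- structure(
    list(t = t, phase = state$current_phase, active_channels = channels,
         params = stim_of_channels(config, channels)),
    class = "stim_command"
  )
  list(state = state, command = cmd)
}

#' Run the controller over a full IMU trace
#'
#' Streams samples through [step_controller()] and collects the command log.
#' An emergency stop (and optional reset) can be injected at given times to
#' exercise the safety interlock.
#'
#' @param samples Data frame with columns `t`, `ax`, `ay`.
#' @param config A [task_config()].
#' @param emergency_stop_at Optional time (s); the stop is latched before
#'   processing the first sample with `t >= emergency_stop_at`.
#' @param reset_at Optional time (s) at which the latch is cleared.
#' @return A `command_log` data frame: `t`, `phase`, `active_channels`
#'   (semicolon-separated ids, `""` when off), `frequency_hz`,
#'   `pulse_width_us`, `intensity_pct` (0 when off). The final
#'   `controller_state` is attached as attribute `"state"`.
#' @export
run_controller <- function(samples, config, emergency_stop_at = NULL,
                           reset_at = NULL) {
  samples <- as.data.frame(samples)
  state <- new_controller_state()
  n <- nrow(samples)
  t_out <- numeric(n); phase <- character(n); ch <- character(n)
  fr <- numeric(n); pw <- numeric(n); it <- numeric(n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    ti <- samples$t[i]
    if (!is.null(emergency_stop_at) && is.finite(ti) &&
        ti >= emergency_stop_at)
      state <- trigger_emergency_stop(state)
    if (!is.null(reset_at) && is.finite(ti) && ti >= reset_at)
      state <- reset_emergency_stop(state)
    res <- step_controller(state, samples[i, ], config)
    state <- res$state
    if (is.null(res$command)) next
    cmd <- res$command
    kept[i] <- TRUE
    t_out[i] <- cmd$t
    phase[i] <- if (is.na(cmd$phase)) "" else cmd$phase
    ch[i] <- paste(cmd$active_channels, collapse = ";")
    on <- length(cmd$active_channels) > 0L
    fr[i] <- if (on) cmd$params$frequency_hz else 0
    pw[i] <- if (on) cmd$params$pulse_width_us else 0
    it[i] <- if (on) cmd$params$intensity_pct else 0
  }
  log <- data.frame(
    t = t_out[kept], phase = phase[kept], active_channels = ch[kept],
    frequency_hz = fr[kept], pulse_width_us = pw[kept],
    intensity_pct = it[kept],
    stringsAsFactors = FALSE
  )
  class(log) <- c("command_log", "data.frame")
  attr(log, "state") <- state
  log
}

#' Build the two-phase pedaling configuration
#'
#' Phase `flexion` activates channels 1 and 2 (right quadriceps, left
#' hamstring) for 150-175 degrees; phase `extension` activates channels 3
#' and 4 (left quadriceps, right hamstring) for -179 to -150 degrees.
#' Angles outside both ranges command all channels off. Stimulation defaults
#' to 35 Hz, 300 us, 75% of maximum.
#'
#' @param stim A [stim_params()] (default 35 Hz / 300 us / 75%).
#' @param min_dwell_s,max_command_rate_hz Passed to [task_config()].
#' @return A `task_config` in pedaling mode.
#' @export
build_pedaling_config <- function(stim = stim_params(35, 300, 75),
                                  min_dwell_s = 0.1,
                                  max_command_rate_hz = 50) {
  task_config(
    "pedaling",
    list(
      phase_definition("flexion", 150, 175, c(1L, 2L),
                       c("right quadriceps", "left hamstring")),
      phase_definition("extension", -179, -150, c(3L, 4L),
                       c("left quadriceps", "right hamstring"))
    ),
    stim = stim, min_dwell_s = min_dwell_s,
    max_command_rate_hz = max_command_rate_hz
  )
}

# Channel convention: 1-4 device A (right leg), 5-8 device B (left leg).
# 1/5 quadriceps, 2/6 hamstring, 3/7 tibialis anterior, 4/8 triceps surae.
gait_muscle_map <- list(
  initial_contact = list(
    channels = c(1L, 3L, 5L, 7L),
    muscles = c("right quadriceps", "right tibialis anterior",
                "left quadriceps", "left tibialis anterior")),
  mid_stance = list(
    channels = c(1L, 5L),
    muscles = c("right quadriceps", "left quadriceps")),
  terminal_stance = list(
    channels = c(1L, 4L, 5L, 8L),
    muscles = c("right quadriceps", "right triceps surae",
                "left quadriceps", "left triceps surae")),
  initial_swing = list(
    channels = c(2L, 3L, 6L, 7L),
    muscles = c("right hamstring", "right tibialis anterior",
                "left hamstring", "left tibialis anterior"))
)

#' Build the four-phase gait configuration
#'
#' The gait cycle is divided into initial contact (quadriceps + tibialis
#' anterior), mid-stance (quadriceps), terminal stance (quadriceps +
#' triceps surae) and initial swing (hamstrings + tibialis anterior), each
#' muscle group on both legs over the 8 channels (1-4 right leg, 5-8 left
#' leg). Angle ranges are therapist-adjustable and therefore a mandatory
#' argument; the defaults simply quarter the circle and are a software
#' default, not a clinical recommendation.
#'
#' @param angle_ranges Named list of 4 inclusive `c(min, max)` degree ranges
#'   in cycle order: `initial_contact`, `mid_stance`, `terminal_stance`,
#'   `initial_swing`. Must be pairwise disjoint.
#' @param stim A [stim_params()].
#' @param min_dwell_s,max_command_rate_hz Passed to [task_config()].
#' @return A `task_config` in gait mode.
#' @export
build_gait_config <- function(angle_ranges = list(
                                initial_contact = c(-180, -91),
                                mid_stance = c(-90, -1),
                                terminal_stance = c(0, 89),
                                initial_swing = c(90, 179)),
                              stim = stim_params(35, 300, 75),
                              min_dwell_s = 0.1,
                              max_command_rate_hz = 50) {
  if (!is.list(angle_ranges) || length(angle_ranges) != 4L ||
      !setequal(names(angle_ranges), names(gait_muscle_map)))
    stop("angle_ranges must be a named list of 4 ranges: ",
         paste(names(gait_muscle_map), collapse = ", "))
  phases <- lapply(names(gait_muscle_map), function(nm) {
    r <- angle_ranges[[nm]]
    if (length(r) != 2L) stop(sprintf("range for '%s' must be c(min, max)",
                                      nm))
    phase_definition(nm, r[1L], r[2L], gait_muscle_map[[nm]]$channels,
                     gait_muscle_map[[nm]]$muscles)
  })
  task_config("gait", phases, stim = stim, min_dwell_s = min_dwell_s,
              max_command_rate_hz = max_command_rate_hz)
}

#' Write a task configuration to YAML
#'
#' @param config A [task_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task_config <- function(config, path) {
  stopifnot(inherits(config, "task_config"))
  s1 <- config$stim[[1L]]
  yaml::write_yaml(list(
    mode = config$mode,
    phases = lapply(config$phases, function(p)
      list(name = p$name, theta_min = p$theta_min, theta_max = p$theta_max,
           channels = as.integer(p$channels), muscles = p$muscles)),
    stim = list(frequency_hz = s1$frequency_hz,
                pulse_width_us = s1$pulse_width_us,
                intensity_pct = s1$intensity_pct,
                sample_rate_hz = s1$sample_rate_hz),
    min_dwell_s = config$min_dwell_s,
    max_command_rate_hz = config$max_command_rate_hz
  ), path)
  invisible(path)
}

#' Read a task configuration from YAML
#'
#' @param path YAML file written by [write_task_config()] (or hand-edited
#'   with the same keys).
#' @return A validated `task_config`.
#' @export
read_task_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  for (k in c("mode", "phases")) if (is.null(y[[k]]))
    stop("config is missing required key: ", k)
  stim <- if (is.null(y$stim)) stim_params() else
    stim_params(y$stim$frequency_hz %||% 35, y$stim$pulse_width_us %||% 300,
                y$stim$intensity_pct %||% 75,
                y$stim$sample_rate_hz %||% 1e5)
  phases <- lapply(y$phases, function(p)
    phase_definition(p$name, p$theta_min, p$theta_max,
                     as.integer(unlist(p$channels)),
                     as.character(unlist(p$muscles))))
  task_config(y$mode, phases, stim = stim,
              min_dwell_s = y$min_dwell_s %||% 0.1,
              max_command_rate_hz = y$max_command_rate_hz %||% 50)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a command log to CSV
#'
#' @param log A `command_log` from [run_controller()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_command_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Read a command log from CSV
#'
#' @param path CSV written by [write_command_log()].
#' @return A `command_log` data frame.
#' @export
read_command_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(phase = "character",
                                        active_channels = "character"))
  log$phase[is.na(log$phase)] <- ""
  log$active_channels[is.na(log$active_channels)] <- ""
  class(log) <- c("command_log", "data.frame")
  log
}
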