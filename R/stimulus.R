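#' Displacement amplitude for a velocity-matched sinusoidal trajectory
#'
#' The rocking platform offered a fast (0.24 Hz) and a slow (0.16 Hz)
#' frequency; to keep the peak velocity identical (0.1 m/s) across
#' frequencies the displacement amplitude is adapted as
#' `A = v_peak / (2 * pi * f)`.  At the study's settings this yields
#' 0.066 m for the fast and 0.10 m for the slow frequency.
#'
#' @param frequency rocking frequency in Hz (> 0).
#' @param peak_velocity target peak velocity in m/s.
#' @return Amplitude in meters (unrounded; round at the caller for
#'   reporting).
#' @export
amplitude_for_velocity <- function(frequency, peak_velocity = 0.1) {
  if (any(frequency <= 0)) stop("frequency must be positive")
  peak_velocity / (2 * pi * frequency)
}

#' Sinusoidal trajectory specification
#'
#' Idealized platform motion along one axis: position
#' `A * sin(2*pi*f*t)` with peak velocity `2*pi*f*A`.  For the rotational
#' axes (roll, pitch) the amplitude is in radians and the "velocity" is a
#' nominal angular rate: no lever arm is modeled, so tangential speeds at
#' the sleeper are not calibrated.
#'
#' @param axis one of `"x"`, `"y"`, `"z"`, `"roll"`, `"pitch"`.
#' @param frequency Hz (the study used 0.16 or 0.24).
#' @param amplitude meters (translations) or radians (rotations); if
#'   `NULL`, derived from `peak_velocity` via [amplitude_for_velocity()].
#' @param peak_velocity m/s (or rad/s, nominal, for rotations).
#' @return List of class `trajectory_spec`.
#' @export
trajectory_spec <- function(axis = c("x", "y", "z", "roll", "pitch"),
                            frequency = 0.16, amplitude = NULL,
                            peak_velocity = 0.1) {
  axis <- match.arg(axis)
  if (frequency <= 0) stop("frequency must be positive")
  if (is.null(amplitude)) {
    amplitude <- amplitude_for_velocity(frequency, peak_velocity)
  } else {
    peak_velocity <- 2 * pi * frequency * amplitude
  }
  structure(list(axis = axis, frequency = frequency, amplitude = amplitude,
                 peak_velocity = peak_velocity),
            class = "trajectory_spec")
}

#' Evaluate a trajectory
#'
#' @param spec a [trajectory_spec()].
#' @param t time(s) in seconds, `>= 0`.
#' @return `data.frame` with `t`, `position` and `velocity`.
#' @export
trajectory <- function(spec, t) {
  stopifnot(inherits(spec, "trajectory_spec"), all(t >= 0))
  w <- 2 * pi * spec$frequency
  data.frame(t = t,
             position = spec$amplitude * sin(w * t),
             velocity = w * spec$amplitude * cos(w * t))
}

#' Per-night stimulation timeline
#'
#' The condition design of the study, as on/noise intervals in seconds
#' after lights out:
#' * `B` (baseline): no motion; pre-recorded platform noise for the first
#'   2 h.
#' * `C1` (motion until sleep onset): motion from lights out until the end
#'   of the third epoch of the first run of 3 consecutive N2 epochs, then
#'   pre-recorded noise until 2 h after lights out.
#' * `C2` (motion for 2 h): motion for the full first 2 h, no noise
#'   playback.
#'
#' When a C1 hypnogram never reaches 3 consecutive N2 epochs, stimulation
#' runs the full 2-h window (with a warning) and no noise is played.
#'
#' @param condition `"B"`, `"C1"` or `"C2"`.
#' @param h the night's [hypnogram()] (required for C1).
#' @param window_s stimulation window length in seconds (default 7200).
#' @return List of class `stimulation_timeline` with `condition`,
#'   `on_interval` and `noise_interval` (each `c(start, end)` in seconds
#'   after lights out, or `NULL` when empty).
#' @export
build_timeline <- function(condition = c("B", "C1", "C2"), h = NULL,
                           window_s = 7200) {
  condition <- match.arg(condition)
  tl <- switch(condition,
    B = list(on_interval = NULL, noise_interval = c(0, window_s)),
    C2 = list(on_interval = c(0, window_s), noise_interval = NULL),
    C1 = {
      if (is.null(h)) stop("C1 timeline requires the night's hypnogram")
      off_epoch <- withCallingHandlers(
        stimulation_off_epoch_c1(h),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.na(off_epoch)) {
        warning("C1 night without 3 consecutive N2 epochs: stimulation ran full window")
        list(on_interval = c(0, window_s), noise_interval = NULL)
      } else {
        # stimulation stops at the end of the third N2 epoch of the run
        off_s <- min(( off_epoch - h$lights_out_epoch + 1) * h$epoch_length,
                     window_s)
        list(on_interval = c(0, off_s),
             noise_interval = if (off_s < window_s) c(off_s, window_s) else NULL)
      }
    })
  structure(c(list(condition = condition), tl), class = "stimulation_timeline")
}
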