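# Filter design helpers shared by the spindle and slow-wave detectors.
#
# All detection filters in this package are applied forward and backward
# (zero phase), so the realized amplitude response is |H(f)|^2.  The study
# protocol pins the -3 dB points of each filter, not its design formula;
# corner parameters are therefore tuned numerically so that the realized
# (two-pass) response crosses -3 dB exactly at the stated frequencies.

# Single-pass amplitude gain of an IIR filter at frequencies f (Hz).
iir_gain <- function(filt, f, fs) {
  b <- filt$b
  a <- filt$a
  vapply(f, function(fi) {
    z <- exp(-2i * pi * fi / fs)
    num <- sum(b * z^(seq_along(b) - 1))
    den <- sum(a * z^(seq_along(a) - 1))
    Mod(num / den)
  }, numeric(1))
}

#' Realized amplitude response of a zero-phase (forward-backward) filter
#'
#' Probes the frequency response actually applied by [filtfilt_zp()]:
#' the squared single-pass magnitude of the filter.
#'
#' @param filt a filter object with `b`/`a` coefficients (e.g. from
#'   [design_sigma_filter()] or the slow-wave cascade components).
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return Amplitude gain (linear) at each frequency.
#' @export
zero_phase_gain <- function(filt, f, fs) iir_gain(filt, f, fs)^2

#' Locate a realized -3 dB point by probing
#'
#' Finds the frequency in `interval` at which the forward-backward gain of
#' `filt` crosses 1/sqrt(2), by root finding on the realized response.
#'
#' @param filt filter object.
#' @param interval numeric length-2 search interval in Hz that brackets
#'   the crossing.
#' @param fs sampling rate in Hz.
#' @return Frequency in Hz.
#' @export
find_minus3db <- function(filt, interval, fs) {
  stats::uniroot(function(f) zero_phase_gain(filt, f, fs) - 1 / sqrt(2),
                 interval, tol = 1e-8)$root
}

# Zero-phase application of an IIR filter.
filtfilt_zp <- function(filt, x) signal::filtfilt(filt, x)

# design cache, keyed by a descriptive string
.filter_cache <- new.env(parent = emptyenv())

cached_design <- function(key, builder) {
  if (!exists(key, envir = .filter_cache)) {
    assign(key, builder(), envir = .filter_cache)
  }
  get(key, envir = .filter_cache)
}

#' Sigma-band spindle filter
#'
#' Band-pass used by the spindle detector: an 8th-order IIR band-pass
#' (4th-order Butterworth prototype) applied forward and backward, with
#' design corners tuned so that the realized zero-phase response is -3 dB
#' at `low` and `high` Hz (defaults 12 and 15 Hz, the sigma band of the
#' detection algorithm).
#'
#' @param fs sampling rate in Hz (>= 64).
#' @param low,high target realized -3 dB points in Hz.
#' @return A `signal::Arma`-style filter object with fields `b`, `a`.
#' @export
design_sigma_filter <- function(fs, low = 12, high = 15) {
  if (fs < 64) stop("sampling rate must be >= 64 Hz for the sigma filter")
  key <- sprintf("sigma_%g_%g_%g", fs, low, high)
  cached_design(key, function() {
    target <- 2^(-1 / 4)  # single-pass gain giving -3 dB after two passes
    bp <- function(lo, hi) signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
    lo <- low
    hi <- high
    for (i in 1:3) {
      lo <- stats::uniroot(function(w) iir_gain(bp(w, hi), low, fs) - target,
                           c(max(0.5, low - 4), low), tol = 1e-6)$root
      hi <- stats::uniroot(function(w) iir_gain(bp(lo, w), high, fs) - target,
                           c(high, min(high + 4, fs / 2 - 0.5)), tol = 1e-6)$root
    }
    bp(lo, hi)
  })
}

#' Slow-wave detection filter cascade
#'
#' The two components of the slow-oscillation preprocessing at 128 Hz: a
#' 3rd-order Chebyshev type II high-pass and a 6th-order Chebyshev type II
#' low-pass, each applied forward and backward.  Stop-band attenuation is
#' 20 dB; the stop-band corner of each filter is tuned so that the
#' realized zero-phase -3 dB points sit at `hp_3db` (default 0.4 Hz) and
#' `lp_3db` (default 2.3 Hz).
#'
#' @param fs sampling rate in Hz (the detector runs at 128 Hz).
#' @param hp_3db,lp_3db target realized -3 dB points in Hz.
#' @param rs stop-band attenuation in dB used for both designs.
#' @return List with components `hp` and `lp` (filter objects).
#' @export
design_sw_cascade <- function(fs = 128, hp_3db = 0.4, lp_3db = 2.3, rs = 20) {
  key <- sprintf("sw_%g_%g_%g_%g", fs, hp_3db, lp_3db, rs)
  cached_design(key, function() {
    target <- 2^(-1 / 4)
    hp_at <- function(w) signal::cheby2(3, rs, w / (fs / 2), type = "high")
    lp_at <- function(w) signal::cheby2(6, rs, w / (fs / 2), type = "low")
    w_hp <- stats::uniroot(function(w) iir_gain(hp_at(w), hp_3db, fs) - target,
                           c(hp_3db / 20, hp_3db * 0.999), tol = 1e-8)$root
    w_lp <- stats::uniroot(function(w) iir_gain(lp_at(w), lp_3db, fs) - target,
                           c(lp_3db * 1.001, lp_3db * 5), tol = 1e-8)$root
    list(hp = hp_at(w_hp), lp = lp_at(w_lp))
  })
}
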