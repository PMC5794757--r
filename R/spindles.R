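#' Sigma-band filtering for spindle detection
#'
#' Zero-phase band-pass of the derivation signal between 12 and 15 Hz
#' (realized -3 dB at both edges; see [design_sigma_filter()]).
#'
#' @param x numeric signal in microvolts.
#' @param fs sampling rate in Hz (>= 64).
#' @param low,high realized -3 dB points in Hz.
#' @return Filtered signal, same length.
#' @export
sigma_filter <- function(x, fs, low = 12, high = 15) {
  filt <- design_sigma_filter(fs, low, high)
  if (any(!is.finite(filt$b)) || any(!is.finite(filt$a)))
    stop("unstable sigma filter design")
  filtfilt_zp(filt, x)
}

# Instantaneous amplitude (upper envelope) of a narrow-band signal via the
# analytic signal.  For a pure sinusoid of amplitude a the envelope is a,
# so thresholds expressed in amplitude units apply directly.
signal_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  hmul <- numeric(n)
  if (n %% 2 == 0) {
    hmul[1] <- 1; hmul[n / 2 + 1] <- 1
    hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1
    hmul[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * hmul, inverse = TRUE) / n)
}

# per-sample eligibility mask: samples inside artifact-free epochs of the
# given stages
sample_mask <- function(h, fs, stages = c("N1", "N2", "N3"), n_samples) {
  spe <- as.integer(round(h$epoch_length * fs))
  ok <- h$stages %in% stages & !h$artifact
  m <- rep(ok, each = spe)
  length(m) <- n_samples           # pad with NA then fix
  m[is.na(m)] <- FALSE
  m
}

#' Spindle detection thresholds
#'
#' The detection thresholds derive from the mean rectified amplitude of
#' the sigma-filtered signal over all artifact-free NREM samples: the
#' lower threshold is 2x and the upper threshold 6x this mean.  Because
#' both thresholds are proportional to the signal's own amplitude, the
#' detector is invariant to overall amplitude scaling.
#'
#' @param filtered sigma-filtered signal (from [sigma_filter()]), aligned
#'   so that sample 1 is the start of epoch 0.
#' @param h the matching [hypnogram()].
#' @param fs sampling rate in Hz.
#' @param nrem_stages stages treated as NREM.
#' @return List of class `spindle_thresholds`: `mean_rectified_amplitude`,
#'   `lower` (= 2x mean), `upper` (= 6x mean), all in microvolts; `NA`s
#'   with a warning when no eligible epoch exists.
#' @export
estimate_thresholds <- function(filtered, h, fs,
                                nrem_stages = c("N1", "N2", "N3")) {
  mask <- sample_mask(h, fs, nrem_stages, length(filtered))
  if (!any(mask)) {
    warning("no artifact-free NREM samples; spindle thresholds undefined")
    return(structure(list(mean_rectified_amplitude = NA_real_,
                          lower = NA_real_, upper = NA_real_),
                     class = "spindle_thresholds"))
  }
  m <- mean(abs(filtered[mask]))
  structure(list(mean_rectified_amplitude = m, lower = 2 * m, upper = 6 * m),
            class = "spindle_thresholds")
}

#' Detect sleep spindles
#'
#' Amplitude-threshold detection on the sigma-filtered signal: a spindle
#' is flagged wherever the signal's instantaneous amplitude (envelope of
#' the rectified band-passed signal) exceeds the upper threshold (6x the
#' mean rectified NREM amplitude) inside artifact-free NREM sleep.  Event
#' boundaries are extended outward to the nearest crossings of the lower
#' threshold (2x mean); events whose lower-threshold extents touch or
#' overlap are merged (optional); events with duration outside
#' `duration_bounds` are discarded.
#'
#' @param filtered sigma-filtered signal aligned to the hypnogram.
#' @param thresholds a [estimate_thresholds()] result for the same signal.
#' @param h the matching [hypnogram()].
#' @param fs sampling rate in Hz.
#' @param duration_bounds admissible event duration in seconds (default
#'   `c(0.3, 3)`).
#' @param merge merge events whose lower-threshold extents touch
#'   (default `TRUE`).
#' @param nrem_stages stages treated as NREM.
#' @return `data.frame` with one row per spindle: `onset`, `offset`
#'   (seconds from recording start), `duration`, `peak_amplitude` (uV,
#'   envelope peak) and `epoch_index` (0-based epoch containing the
#'   onset).
#' @export
detect_spindles <- function(filtered, thresholds, h, fs,
                            duration_bounds = c(0.3, 3), merge = TRUE,
                            nrem_stages = c("N1", "N2", "N3")) {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), peak_amplitude = numeric(0),
                      epoch_index = integer(0))
  if (is.na(thresholds$upper)) return(empty)
  env <- signal_envelope(filtered)
  mask <- sample_mask(h, fs, nrem_stages, length(filtered))
  above_upper <- env > thresholds$upper & mask
  if (!any(above_upper)) return(empty)
  below_lower <- env < thresholds$lower
  n <- length(env)
  # for each sample, index of the nearest below-lower sample at/before it
  prev_below <- cummax(ifelse(below_lower, seq_len(n), 0L))
  next_below <- n + 1L - rev(cummax(rev(ifelse(below_lower, n + 1L - seq_len(n), 0L))))
  r <- rle(above_upper)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ex_start <- starts[r$values]
  ex_end <- ends[r$values]
  lo <- prev_below[ex_start] + 1L          # first supra-lower sample
  hi <- next_below[ex_end] - 1L            # last supra-lower sample
  lo[lo < 1L] <- 1L
  hi[hi > n] <- n
  iv <- unique(data.frame(lo = lo, hi = hi))
  iv <- iv[order(iv$lo, iv$hi), , drop = FALSE]
  if (merge && nrow(iv) > 1L) {
    keep_lo <- iv$lo[1L]; keep_hi <- iv$hi[1L]
    out_lo <- integer(0); out_hi <- integer(0)
    for (i in seq_len(nrow(iv))[-1L]) {
      if (iv$lo[i] <= keep_hi + 1L) {
        keep_hi <- max(keep_hi, iv$hi[i])
      } else {
        out_lo <- c(out_lo, keep_lo); out_hi <- c(out_hi, keep_hi)
        keep_lo <- iv$lo[i]; keep_hi <- iv$hi[i]
      }
    }
    iv <- data.frame(lo = c(out_lo, keep_lo), hi = c(out_hi, keep_hi))
  }
  dur <- (iv$hi - iv$lo + 1L) / fs
  ok <- dur >= duration_bounds[1L] & dur <= duration_bounds[2L]
  iv <- iv[ok, , drop = FALSE]
  dur <- dur[ok]
  if (nrow(iv) == 0L) return(empty)
  peak <- vapply(seq_len(nrow(iv)),
                 function(i) max(env[iv$lo[i]:iv$hi[i]]), numeric(1))
  onset <- (iv$lo - 1L) / fs
  data.frame(onset = onset, offset = iv$hi / fs, duration = dur,
             peak_amplitude = peak,
             epoch_index = as.integer(onset %/% h$epoch_length))
}

#' Spindle count and density over a window
#'
#' Counts events whose onset lies in an artifact-free NREM epoch of the
#' window; density is the count per eligible 20-s epoch (the study's
#' "spindles per 20-s epoch" measure).
#'
#' @param events `data.frame` from [detect_spindles()].
#' @param h the matching [hypnogram()].
#' @param window [analysis_window()] or `NULL` for the entire night.
#' @param nrem_stages stages treated as NREM.
#' @return List with `count` and `density`; density is `NA` (with a
#'   warning) when the window contains no eligible epoch.
#' @export
spindle_counts <- function(events, h, window = NULL,
                           nrem_stages = c("N1", "N2", "N3")) {
  idx <- window_indices(h, window)
  eligible <- idx[h$stages[idx] %in% nrem_stages & !h$artifact[idx]]
  if (length(eligible) == 0L) {
    warning("no artifact-free NREM epoch in window; density undefined")
    return(list(count = 0L, density = NA_real_))
  }
  in_window <- (events$epoch_index + 1L) %in% eligible
  count <- sum(in_window)
  list(count = as.integer(count), density = count / length(eligible))
}
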