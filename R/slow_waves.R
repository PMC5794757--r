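#' Slow-wave preprocessing
#'
#' Prepares the frontal derivation for half-wave detection: the signal is
#' decimated to 128 Hz (zero-phase anti-alias low-pass, then subsampling)
#' and band-limited to the slow-oscillation range with a 3rd-order
#' Chebyshev type II high-pass (-3 dB at 0.4 Hz) followed by a 6th-order
#' Chebyshev type II low-pass (-3 dB at 2.3 Hz), each applied forward and
#' backward so that no phase distortion is introduced (see
#' [design_sw_cascade()]).
#'
#' @param x numeric signal in microvolts.
#' @param fs input sampling rate in Hz; must be an integer multiple of
#'   `target_fs`.
#' @param target_fs detection sampling rate (default 128 Hz).
#' @param hp_3db,lp_3db realized -3 dB points of the cascade in Hz.
#' @return Filtered signal at `target_fs`.
#' @export
sw_preprocess <- function(x, fs, target_fs = 128, hp_3db = 0.4, lp_3db = 2.3) {
  if (fs < target_fs || (fs %% target_fs) != 0)
    stop(sprintf("sampling rate must be an integer multiple of %g Hz", target_fs))
  q <- as.integer(fs / target_fs)
  if (q > 1L) {
    aa <- cached_design(sprintf("aa_%d_%g", q, fs), function() {
      signal::butter(8, 0.8 / q, type = "low")
    })
    x <- filtfilt_zp(aa, x)
    x <- x[seq.int(1L, length(x), by = q)]
  }
  cas <- design_sw_cascade(target_fs, hp_3db, lp_3db)
  if (any(!is.finite(unlist(cas$hp))) || any(!is.finite(unlist(cas$lp))))
    stop("unstable slow-wave filter design")
  filtfilt_zp(cas$lp, filtfilt_zp(cas$hp, x))
}

#' Detect slow-oscillation half-waves
#'
#' Segments the preprocessed signal at zero-line crossings (sign changes
#' between consecutive samples) and emits one event per segment whose
#' maximum unsigned excursion reaches the amplitude criterion of 37.5 uV
#' (75 uV peak-to-peak).  Positive and negative half-waves are both
#' counted as slow oscillations.  Segment boundaries are refined to
#' sub-sample precision by linear interpolation (reporting only; the
#' criterion is evaluated on samples).
#'
#' @param x preprocessed signal from [sw_preprocess()].
#' @param fs sampling rate of `x` in Hz (default 128).
#' @param amplitude_criterion minimum unsigned peak amplitude in uV.
#' @param epoch_length scoring epoch length in seconds, used to assign
#'   `epoch_index`.
#' @return `data.frame` with one row per half-wave: `polarity`
#'   (`"positive"`/`"negative"`), `start`, `end` (seconds, interpolated
#'   zero crossings), `peak_amplitude` (uV, unsigned), `peak_time`
#'   (seconds) and `epoch_index` (0-based epoch containing the start).
#' @export
detect_half_waves <- function(x, fs = 128, amplitude_criterion = 37.5,
                              epoch_length = 20) {
  n <- length(x)
  empty <- data.frame(polarity = character(0), start = numeric(0),
                      end = numeric(0), peak_amplitude = numeric(0),
                      peak_time = numeric(0), epoch_index = integer(0))
  if (n < 2L) return(empty)
  s <- sign(x)
  # exact zeros adopt the preceding sign so that crossings are resolved by
  # sign changes between consecutive samples
  for (i in which(s == 0)) s[i] <- if (i > 1L) s[i - 1L] else 1
  chg <- which(s[-1L] != s[-n]) # crossing between sample chg and chg+1
  bounds <- c(0L, chg, n)       # segment i: samples (bounds[i]+1)..bounds[i+1]
  out <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i] + 1L
    b <- bounds[i + 1L]
    if (b - a + 1L < 2L) next   # degenerate segment
    seg <- x[a:b]
    pk <- which.max(abs(seg))
    amp <- abs(seg[pk])
    if (amp < amplitude_criterion) next
    # sub-sample zero-crossing times (seconds; sample k is at (k-1)/fs)
    t0 <- if (a > 1L) {
      f <- x[a - 1L] / (x[a - 1L] - x[a])
      (a - 2L + f) / fs
    } else 0
    t1 <- if (b < n) {
      f <- x[b] / (x[b] - x[b + 1L])
      (b - 1L + f) / fs
    } else (n - 1L) / fs
    out[[i]] <- data.frame(
      polarity = if (seg[pk] > 0) "positive" else "negative",
      start = t0, end = t1, peak_amplitude = amp,
      peak_time = (a + pk - 2L) / fs,
      epoch_index = as.integer(t0 %/% epoch_length),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Slow-oscillation count and density over a window
#'
#' Counts half-waves (both polarities combined, as the study reports one
#' combined slow-oscillation count) whose start lies in an eligible epoch
#' of the window; density is the count per eligible 20-s epoch.  By
#' default events are restricted to artifact-free NREM epochs, consistent
#' with the spindle statistics; `all_sleep = TRUE` relaxes the stage
#' restriction to any artifact-free non-W epoch.
#'
#' @param events `data.frame` from [detect_half_waves()].
#' @param h the matching [hypnogram()].
#' @param window [analysis_window()] or `NULL` for the entire night.
#' @param nrem_stages stages treated as NREM.
#' @param all_sleep count over all artifact-free sleep epochs instead of
#'   NREM only.
#' @return List with `count`, `density`, and per-polarity counts
#'   `count_positive` / `count_negative`.
#' @export
so_counts <- function(events, h, window = NULL,
                      nrem_stages = c("N1", "N2", "N3"), all_sleep = FALSE) {
  idx <- window_indices(h, window)
  stages_ok <- if (all_sleep) h$stages[idx] != "W"
               else h$stages[idx] %in% nrem_stages
  eligible <- idx[stages_ok & !h$artifact[idx]]
  if (length(eligible) == 0L) {
    warning("no eligible epoch in window; slow-oscillation density undefined")
    return(list(count = 0L, density = NA_real_,
                count_positive = 0L, count_negative = 0L))
  }
  in_window <- (events$epoch_index + 1L) %in% eligible
  count <- sum(in_window)
  list(count = as.integer(count),
       density = count / length(eligible),
       count_positive = as.integer(sum(in_window & events$polarity == "positive")),
       count_negative = as.integer(sum(in_window & events$polarity == "negative")))
}
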