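#' Construct a continuous EEG recording
#'
#' Multichannel signal in microvolts at a fixed sampling rate.  Channel
#' labels follow the 10-20 system; `reference` names the recording
#' reference (the study's amplifier referenced all channels to Cz and
#' analyses were run after re-referencing to the contralateral mastoid).
#'
#' @param samples numeric matrix, channels x time, in microvolts.  A plain
#'   vector is treated as a single channel.
#' @param sampling_rate sampling rate in Hz (the study recorded at 256 Hz).
#' @param channel_labels character vector, one label per row.
#' @param reference reference label (default `"Cz"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate,
                          channel_labels = NULL, reference = "Cz") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric channels x time matrix")
  if (is.null(channel_labels)) {
    channel_labels <- rownames(samples)
    if (is.null(channel_labels))
      channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples))
    stop("one channel label per row required")
  rownames(samples) <- channel_labels
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         channel_labels = channel_labels, reference = reference),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f min), ref %s\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate / 60, x$reference))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Re-reference to a bipolar derivation
#'
#' Computes a mastoid derivation such as C3-A2 from common-reference
#' inputs: with both channels recorded against the same reference,
#' (C3 - ref) - (A2 - ref) = C3 - A2, so the common reference cancels.
#'
#' @param rec an [eeg_recording()].
#' @param derivation string `"<active>-<reference>"`, e.g. `"C3-A2"`.
#' @return A single-channel `eeg_recording` labelled with the derivation.
#' @export
rereference <- function(rec, derivation) {
  stopifnot(inherits(rec, "eeg_recording"))
  parts <- strsplit(derivation, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("derivation must be of the form 'C3-A2'")
  for (ch in parts) {
    if (!ch %in% rec$channel_labels)
      stop(sprintf("channel '%s' not present in recording", ch))
  }
  x <- rec$samples[parts[1L], ] - rec$samples[parts[2L], ]
  eeg_recording(matrix(x, nrow = 1L), rec$sampling_rate,
                channel_labels = derivation, reference = parts[2L])
}

#' Per-epoch power spectra (Hanning-windowed FFT)
#'
#' For each 20-s scoring epoch the spectrum is the mean of 5 non-overlapping
#' 4-s Hanning-windowed periodograms, giving 0.25 Hz frequency resolution.
#' Normalization is one-sided with window-power (noise-gain) correction so
#' that summing bins over a band yields absolute power in uV^2: a pure
#' bin-centered sinusoid of amplitude a integrates to a^2/2.
#'
#' @param rec single-channel [eeg_recording()] aligned so that sample 1 is
#'   the start of the hypnogram's first epoch.
#' @param h the matching [hypnogram()].
#' @return An object of class `epoch_spectra`: list with `power`
#'   (epochs x frequency matrix, uV^2 per bin), `freq` (Hz) and
#'   `sampling_rate`.
#' @export
epoch_spectra <- function(rec, h) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(h, "hypnogram"))
  if (nrow(rec$samples) != 1L)
    stop("epoch_spectra expects a single-derivation recording; use rereference()")
  fs <- rec$sampling_rate
  nblock <- as.integer(round(4 * fs))          # 4-s FFT blocks
  blocks_per_epoch <- as.integer(h$epoch_length / 4)
  spe <- nblock * blocks_per_epoch             # samples per 20-s epoch
  ne <- n_epochs(h)
  need <- ne * spe
  x <- drop(rec$samples)
  if (length(x) < need)
    stop(sprintf("recording too short: %d samples, need %d for %d epochs",
                 length(x), need, ne))
  x <- x[seq_len(need)]
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0, nblock - 1) / nblock)  # periodic Hann
  s2 <- sum(w^2)                               # window noise gain
  m <- matrix(x, nrow = nblock)                # one 4-s block per column
  X <- stats::mvfft(m * w)
  nb <- nblock %/% 2 + 1L
  # one-sided, window-power normalized: band sums give absolute uV^2
  p <- 2 * Mod(X[seq_len(nb), , drop = FALSE])^2 / (nblock * s2)
  p[1L, ] <- p[1L, ] / 2   # DC and Nyquist are not doubled
  p[nb, ] <- p[nb, ] / 2
  # average the 5 blocks of each epoch
  ep <- t(vapply(seq_len(ne), function(e) {
    cols <- ((e - 1L) * blocks_per_epoch + 1L):(e * blocks_per_epoch)
    rowMeans(p[, cols, drop = FALSE])
  }, numeric(nb)))
  structure(list(power = ep, freq = seq.int(0, nb - 1L) * fs / nblock,
                 sampling_rate = fs),
            class = "epoch_spectra")
}

#' Standard analysis bands
#'
#' The study's frequency bands in Hz.  Note that the printed alpha band
#' (9-15 Hz) fully contains the sigma band (11-15 Hz); both are computed
#' independently, as reported.  Band edges shared by adjacent bands (e.g.
#' 4.5 Hz in delta and theta) contribute to both, matching the inclusive
#' printed ranges.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
#' @rdname bands
default_bands <- function() {
  list(delta = c(0.75, 4.5), theta = c(4.5, 9), alpha = c(9, 15),
       sigma = c(11, 15), beta = c(15, 25))
}

#' @details `sub_delta_bands()` gives the finer subdivision of the delta
#'   range used for the slow-oscillation frequency analysis: below 1 Hz,
#'   1-2 Hz and 2-4 Hz.
#' @export
#' @rdname bands
sub_delta_bands <- function() {
  list(delta_lt1 = c(0.25, 0.75), delta_1_2 = c(1, 2), delta_2_4 = c(2, 4))
}

#' Band power per epoch
#'
#' Sums spectral bins whose center frequency f satisfies low <= f <= high
#' (both inclusive); overlapping bands are computed independently.
#'
#' @param spectra an [epoch_spectra()] object.
#' @param bands named list of `c(low, high)` Hz pairs; defaults to
#'   [default_bands()].
#' @return A `band_power_series`: epochs x bands numeric matrix (uV^2)
#'   with the band definitions attached as attribute `"bands"`.
#' @export
band_power <- function(spectra, bands = default_bands()) {
  stopifnot(inherits(spectra, "epoch_spectra"))
  freq <- spectra$freq
  out <- vapply(names(bands), function(bn) {
    b <- bands[[bn]]
    if (length(b) != 2L || b[2L] < b[1L])
      stop(sprintf("band '%s' is empty or malformed", bn))
    if (b[2L] > max(freq) || b[1L] < 0)
      stop(sprintf("band '%s' lies outside the spectral range", bn))
    sel <- freq >= b[1L] & freq <= b[2L]
    if (!any(sel))
      stop(sprintf("band '%s' narrower than the frequency resolution", bn))
    rowSums(spectra$power[, sel, drop = FALSE])
  }, numeric(nrow(spectra$power)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(bands)))
  structure(out, bands = bands, class = c("band_power_series", "matrix"))
}

#' Mean band power over artifact-free NREM epochs
#'
#' The whole-night (or windowed) band means that mirror the study's
#' band-power table: averages over artifact-free epochs staged N1, N2 or
#' N3 (the NREM definition is a parameter).
#'
#' @param series a [band_power()] matrix.
#' @param h the matching [hypnogram()].
#' @param window [analysis_window()] or `NULL` for the entire night.
#' @param nrem_stages stages counted as NREM (default `c("N1","N2","N3")`).
#' @return Named numeric vector, one mean per band; `NA` with a warning
#'   when no eligible epoch exists.
#' @export
nrem_band_means <- function(series, h, window = NULL,
                            nrem_stages = c("N1", "N2", "N3")) {
  idx <- window_indices(h, window)
  ok <- idx[h$stages[idx] %in% nrem_stages & !h$artifact[idx]]
  if (length(ok) == 0L) {
    warning("no artifact-free NREM epoch in window; band means undefined")
    return(stats::setNames(rep(NA_real_, ncol(series)), colnames(series)))
  }
  colMeans(series[ok, , drop = FALSE])
}

#' Delta build-up after sleep onset
#'
#' The time course of delta power across the first hour of sleep: the
#' delta-band sequence for the 180 epochs following sleep onset, smoothed
#' with a centered moving average over 7 epochs (shrinking window at the
#' edges).
#'
#' @param series a [band_power()] matrix containing a `delta` column (or
#'   the column named by `band`).
#' @param h the matching [hypnogram()].
#' @param band band column to use (default `"delta"`).
#' @param n_buildup_epochs number of epochs after onset (default 180 = 1 h).
#' @param k moving-average length in epochs (default 7).
#' @return Numeric vector of length `n_buildup_epochs`.
#' @export
delta_buildup <- function(series, h, band = "delta",
                          n_buildup_epochs = 180L, k = 7L) {
  onset <- sleep_onset_epoch(h)
  if (is.na(onset)) {
    warning("no sleep onset; delta build-up undefined")
    return(rep(NA_real_, n_buildup_epochs))
  }
  from <- onset + 1L  # 1-based index of the onset epoch
  to <- from + n_buildup_epochs - 1L
  if (to > nrow(series))
    stop(sprintf("need %d epochs after sleep onset, have %d",
                 n_buildup_epochs, nrow(series) - from + 1L))
  x <- series[from:to, band]
  half <- (k - 1L) %/% 2L
  vapply(seq_along(x), function(i) {
    mean(x[max(1L, i - half):min(length(x), i + half)])
  }, numeric(1))
}
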