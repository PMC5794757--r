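#' Sleep latency
#'
#' Minutes from lights out to the first occurrence of N2 sleep.  Returns
#' `NA` (with a warning) when no N2 epoch follows lights out: the latency
#' is undefined, not zero.
#'
#' @param h a [hypnogram()].
#' @return Minutes (numeric scalar), or `NA_real_` if undefined.
#' @export
sleep_latency <- function(h) {
  onset <- sleep_onset_epoch(h)
  if (is.na(onset)) {
    warning("no N2 epoch after lights out; sleep latency undefined")
    return(NA_real_)
  }
  (onset - h$lights_out_epoch) * h$epoch_length / 60
}

#' N2 latency from N1
#'
#' Minutes between the first occurrence of N2 and the first occurrence of
#' N1.  Negative when N2 precedes N1 (reported as-is).
#'
#' @inheritParams sleep_latency
#' @return Minutes, possibly negative; `NA_real_` if either stage is absent.
#' @export
n2_latency_from_n1 <- function(h) {
  n1 <- first_stage_epoch(h, "N1")
  n2 <- first_stage_epoch(h, "N2")
  if (is.na(n1) || is.na(n2)) {
    warning("N1 or N2 absent; N2-from-N1 latency undefined")
    return(NA_real_)
  }
  (n2 - n1) * h$epoch_length / 60
}

stage_latency_from_onset <- function(h, stage) {
  onset <- sleep_onset_epoch(h)
  tgt <- first_stage_epoch(h, stage)
  if (is.na(onset) || is.na(tgt)) {
    warning(sprintf("sleep onset or %s absent; latency undefined", stage))
    return(NA_real_)
  }
  (tgt - onset) * h$epoch_length / 60
}

#' Slow-wave-sleep and REM latency
#'
#' Minutes from sleep onset (first N2 epoch) to the first occurrence of N3
#' (`sws_latency`) or REM sleep (`rem_latency`).
#'
#' @inheritParams sleep_latency
#' @return Minutes, or `NA_real_` if undefined.
#' @export
#' @rdname stage_latencies
sws_latency <- function(h) stage_latency_from_onset(h, "N3")

#' @export
#' @rdname stage_latencies
rem_latency <- function(h) stage_latency_from_onset(h, "REM")

#' Minutes spent in a stage within a window
#'
#' @param h a [hypnogram()].
#' @param window an [analysis_window()] relative to lights out, or `NULL`
#'   for the entire night.
#' @param stage one of `STAGES`.
#' @return Minutes.
#' @export
stage_minutes <- function(h, window = NULL, stage) {
  stage <- match.arg(stage, STAGES)
  idx <- window_indices(h, window)
  sum(h$stages[idx] == stage) * h$epoch_length / 60
}

#' Wake after sleep onset
#'
#' Minutes of W strictly after the sleep-onset epoch within the window.
#' Wake before onset counts toward sleep latency only; with no onset yet,
#' WASO is 0.
#'
#' @inheritParams stage_minutes
#' @return Minutes.
#' @export
waso <- function(h, window = NULL) {
  idx <- window_indices(h, window)
  onset <- sleep_onset_epoch(h)
  if (is.na(onset)) return(0)
  idx <- idx[idx - 1L > onset]  # strictly after the onset epoch
  sum(h$stages[idx] == "W") * h$epoch_length / 60
}

#' Sleep efficiency
#'
#' Percentage of window epochs (after lights out) spent in any sleep
#' stage (non-W).
#'
#' @inheritParams stage_minutes
#' @return Percent in `[0, 100]`.
#' @export
sleep_efficiency <- function(h, window = NULL) {
  idx <- window_indices(h, window)
  100 * sum(h$stages[idx] != "W") / length(idx)
}

#' Number of sleep stage changes
#'
#' Adjacent epoch pairs with differing stage labels, counted from the
#' sleep-onset epoch (or the window start, whichever is later) to the end
#' of the window.  The study quantifies this from sleep onset until 2 h
#' after lights out as a sleep-continuity measure.
#'
#' @inheritParams stage_minutes
#' @return Integer count, or `NA_integer_` when no sleep onset occurs
#'   before the window end.
#' @export
stage_changes <- function(h, window = NULL) {
  idx <- window_indices(h, window)
  onset <- sleep_onset_epoch(h)
  if (is.na(onset) || onset + 1L > idx[length(idx)]) {
    warning("no sleep onset before window end; stage changes undefined")
    return(NA_integer_)
  }
  idx <- idx[idx >= onset + 1L]
  if (length(idx) < 2L) return(0L)
  s <- h$stages[idx]
  sum(s[-1L] != s[-length(s)])
}

#' Number of artifact-flagged (excluded) epochs
#'
#' @inheritParams stage_minutes
#' @return Integer count of flagged epochs in the window.
#' @export
excluded_epochs <- function(h, window = NULL) {
  idx <- window_indices(h, window)
  sum(h$artifact[idx])
}

#' Epoch at which C1 stimulation switches off
#'
#' In the stimulation-until-sleep-onset condition (C1) the platform stops
#' after the first occurrence of 3 consecutive N2 epochs.  Returns the
#' 0-based index of the third epoch of that first run; stimulation stops
#' at the *end* of this epoch (see [build_timeline()]).  Runs are searched
#' from lights out.
#'
#' @inheritParams sleep_latency
#' @return 0-based epoch index, or `NA_integer_` (with a warning) when no
#'   such run exists, in which case stimulation runs the full window.
#' @export
stimulation_off_epoch_c1 <- function(h) {
  s <- h$stages[(h$lights_out_epoch + 1L):n_epochs(h)]
  r <- rle(s == "N2")
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= 3L)
  if (length(hit) == 0L) {
    warning("no run of 3 consecutive N2 epochs; stimulation runs full window")
    return(NA_integer_)
  }
  start_of_run <- ends[hit[1L]] - r$lengths[hit[1L]] + 1L
  # third epoch of the run, back to 0-based absolute indexing
  h$lights_out_epoch + start_of_run + 2L - 1L
}

#' Full sleep-architecture report for one window
#'
#' All visually-scored architecture metrics of a night in one tidy row:
#' latencies (full-night properties, reported regardless of window),
#' per-stage minutes, WASO, efficiency, stage changes and excluded-epoch
#' counts for the requested window.
#'
#' @inheritParams stage_minutes
#' @param window_label label stored in the output (e.g. `"entire_night"`,
#'   `"first_2h"`).
#' @return A one-row `data.frame`.
#' @export
architecture_report <- function(h, window = NULL, window_label = "entire_night") {
  sl <- suppressWarnings(sleep_latency(h))
  data.frame(
    window = window_label,
    sleep_latency_min = sl,
    n2_latency_from_n1_min = suppressWarnings(n2_latency_from_n1(h)),
    sws_latency_min = suppressWarnings(sws_latency(h)),
    rem_latency_min = suppressWarnings(rem_latency(h)),
    sleep_efficiency_pct = sleep_efficiency(h, window),
    n1_min = stage_minutes(h, window, "N1"),
    n2_min = stage_minutes(h, window, "N2"),
    n3_min = stage_minutes(h, window, "N3"),
    rem_min = stage_minutes(h, window, "REM"),
    waso_min = waso(h, window),
    stage_changes = suppressWarnings(stage_changes(h, window)),
    excluded_epochs = excluded_epochs(h, window),
    stringsAsFactors = FALSE)
}
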