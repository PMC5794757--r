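#' Sleep stage labels
#'
#' The five stages used throughout the package: wake plus the AASM NREM
#' stages and REM sleep. Hypnograms are scored on 20-s epochs.
#'
#' @format Character vector of length 5.
#' @export
STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Construct an epoched hypnogram
#'
#' The temporal skeleton of every analysis: one stage label per 20-s
#' scoring epoch, an artifact flag per epoch, and the index of the first
#' epoch after lights out.  All epoch indices in this package are 0-based
#' and relative to the start of the recording; analysis windows are
#' half-open epoch ranges relative to lights out.
#'
#' @param stages character vector of stage labels, one per epoch, each in
#'   `STAGES`.
#' @param artifact logical vector of the same length; `TRUE` marks an epoch
#'   excluded from spectral and detector statistics.  Defaults to all clean.
#' @param lights_out_epoch 0-based index of the first epoch after lights
#'   out (default 0: recording starts at lights out).
#' @param epoch_length epoch duration in seconds (fixed at 20 in this
#'   study design; kept as a field for traceability).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, artifact = NULL, lights_out_epoch = 0L,
                      epoch_length = 20) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad) > 0L)
    stop("invalid stage label(s): ", paste(bad, collapse = ", "))
  if (is.null(artifact)) artifact <- rep(FALSE, length(stages))
  artifact <- as.logical(artifact)
  if (length(artifact) != length(stages))
    stop("artifact flags must have one entry per epoch")
  if (anyNA(artifact)) stop("artifact flags must be TRUE/FALSE")
  lights_out_epoch <- as.integer(lights_out_epoch)
  if (lights_out_epoch < 0L || lights_out_epoch >= length(stages))
    stop("lights_out_epoch out of range")
  structure(
    list(stages = stages, artifact = artifact,
         lights_out_epoch = lights_out_epoch,
         epoch_length = as.numeric(epoch_length)),
    class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs (%.1f min), lights out at epoch %d\n",
              length(x$stages), x$epoch_length,
              length(x$stages) * x$epoch_length / 60, x$lights_out_epoch))
  tab <- table(factor(x$stages, levels = STAGES))
  cat("  stages:  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  artifact-flagged epochs: %d\n", sum(x$artifact)))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

n_epochs <- function(h) length(h$stages)

#' Analysis window over a hypnogram
#'
#' Half-open epoch range `[start_epoch, end_epoch)`, 0-based, relative to
#' lights out.  The study's standard windows are the entire night and the
#' first 2 hours after lights out, i.e. epochs `[0, 360)`.
#'
#' @param start_epoch,end_epoch 0-based epoch indices relative to lights
#'   out; `end_epoch` is exclusive.
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(start_epoch, end_epoch) {
  start_epoch <- as.integer(start_epoch)
  end_epoch <- as.integer(end_epoch)
  if (start_epoch < 0L) stop("start_epoch must be >= 0")
  if (start_epoch >= end_epoch) stop("window must satisfy start_epoch < end_epoch")
  structure(list(start_epoch = start_epoch, end_epoch = end_epoch),
            class = "analysis_window")
}

#' Standard analysis windows
#'
#' @param h a `hypnogram` (needed for the entire-night window length).
#' @param hours window length in hours after lights out.
#' @return An `analysis_window`.
#' @export
#' @rdname windows
window_entire_night <- function(h) {
  analysis_window(0L, n_epochs(h) - h$lights_out_epoch)
}

#' @export
#' @rdname windows
window_first_hours <- function(hours = 2) {
  analysis_window(0L, as.integer(round(hours * 3600 / 20)))
}

# Clip a window (relative to lights out) to the hypnogram and return the
# 1-based R indices of the epochs it covers.
window_indices <- function(h, window) {
  if (is.null(window)) window <- window_entire_night(h)
  stopifnot(inherits(window, "analysis_window"))
  lo <- h$lights_out_epoch
  from <- lo + window$start_epoch + 1L
  to <- min(lo + window$end_epoch, n_epochs(h))
  if (from > to) stop("analysis window lies outside the hypnogram")
  from:to
}

# 0-based absolute epoch index of the first epoch at/after lights out with
# the given stage, or NA if absent.
first_stage_epoch <- function(h, stage) {
  idx <- which(h$stages == stage)
  idx <- idx[idx >= h$lights_out_epoch + 1L]
  if (length(idx) == 0L) return(NA_integer_)
  idx[1L] - 1L
}

# Sleep onset epoch (0-based, absolute): first N2 epoch after lights out.
# The study defines sleep latency to N2 and anchors the C1 stimulation
# off-rule on N2, so onset := first N2.
sleep_onset_epoch <- function(h) first_stage_epoch(h, "N2")
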