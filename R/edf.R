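# Minimal EDF (European Data Format) I/O: 16-bit integer storage with
# physical calibration, one-second data records.  Covers the subset of
# the format this package produces and consumes (continuous identical-
# rate signals); it is not a general EDF+ implementation.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Stores all channels as 16-bit integers with symmetric physical range
#' (microvolts) in one-second data records.  The recording length must be
#' a whole number of seconds and the sampling rate an integer.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param patient,recording_id free-text EDF header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "rockpsg") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n <- ncol(rec$samples)
  if (n %% fs != 0)
    stop("recording length must be a whole number of seconds for EDF records")
  nrec <- n %/% fs
  ns <- nrow(rec$samples)
  pmaxs <- apply(abs(rec$samples), 1, max)
  pmaxs[pmaxs == 0] <- 1
  pmaxs <- signif(pmaxs * 1.0001, 7)   # headroom so extremes stay in range
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width), collapse = "")
  hdr <- paste0(hdr,
    field(rec$channel_labels, 16),
    field(rep("", ns), 80),                 # transducer
    field(rep("uV", ns), 8),
    field(format(-pmaxs, trim = TRUE), 8),  # physical min
    field(format(pmaxs, trim = TRUE), 8),   # physical max
    field(rep(-32768, ns), 8),
    field(rep(32767, ns), 8),
    field(rep("", ns), 80),                 # prefiltering
    field(rep(fs, ns), 8),
    field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  scale <- (2 * pmaxs) / 65535
  dig <- round(sweep(rec$samples, 1, scale, "/"))
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns))
      writeBin(as.integer(dig[s, cols]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_ascii <- function(con, width, offset, what) {
  raw <- readBin(con, "raw", width)
  if (length(raw) < width)
    stop(sprintf("malformed EDF header: unexpected end of file at byte %d (%s)",
                 offset + length(raw), what))
  trimws(rawToChar(raw))
}

#' Read an EDF file
#'
#' Parses the header and the 16-bit data records, returning physical
#' (microvolt) values.  All signals must share one sampling rate.
#' Malformed headers raise a parse error naming the byte offset;
#' truncated data records raise an error rather than silently clipping.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  off <- 0
  rd <- function(w, what) {
    out <- read_ascii(con, w, off, what)
    off <<- off + w
    out
  }
  rd(8, "version"); rd(80, "patient"); rd(80, "recording id")
  rd(8, "start date"); rd(8, "start time")
  hbytes <- suppressWarnings(as.integer(rd(8, "header bytes")))
  rd(44, "reserved")
  nrec <- suppressWarnings(as.integer(rd(8, "record count")))
  dur <- suppressWarnings(as.numeric(rd(8, "record duration")))
  ns <- suppressWarnings(as.integer(rd(4, "signal count")))
  if (anyNA(c(hbytes, nrec, dur, ns)) || ns < 1L)
    stop(sprintf("malformed EDF header: unparsable field before byte %d", off))
  if (hbytes != 256 * (ns + 1L))
    stop(sprintf("malformed EDF header: header size field %d at byte 184 does not match %d signals",
                 hbytes, ns))
  rdv <- function(w, what) vapply(seq_len(ns), function(i) rd(w, what), "")
  labels <- rdv(16, "label"); rdv(80, "transducer"); rdv(8, "dimension")
  pmin <- as.numeric(rdv(8, "physical min"))
  pmax <- as.numeric(rdv(8, "physical max"))
  dmin <- as.numeric(rdv(8, "digital min"))
  dmax <- as.numeric(rdv(8, "digital max"))
  rdv(80, "prefiltering")
  spr <- as.integer(rdv(8, "samples per record"))
  rdv(32, "reserved")
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop(sprintf("malformed EDF header: unparsable signal field before byte %d", off))
  if (length(unique(spr / dur)) != 1L)
    stop("signals with differing sampling rates are not supported")
  expect_bytes <- 2 * sum(spr) * nrec
  actual <- file.size(path) - hbytes
  if (actual < expect_bytes)
    stop(sprintf("truncated EDF: %d data bytes present, %d expected from header",
                 actual, expect_bytes))
  out <- matrix(0, nrow = ns, ncol = spr[1L] * nrec)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[s])
        stop(sprintf("truncated EDF data record %d for signal %d", r, s))
      cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      out[s, cols] <- pmin[s] + (v - dmin[s]) * scale[s]
    }
  }
  eeg_recording(out, spr[1L] / dur, channel_labels = labels)
}
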