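# Minimal standard EDF (16-bit) writer/reader.
#
# Covers the plain EDF subset the pipeline needs: one fixed sampling rate
# for all signals, 1-s data records, physical units in microvolts. The
# subject id, session id and eye state travel in the patient-id header
# field so that a cohort written to disk round-trips losslessly (up to the
# 16-bit amplitude quantisation of the format).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param rec an [recording()].
#' @param path output file path.
#' @param phys_range symmetric physical amplitude range in microvolts;
#'   samples outside it are clipped. The default comfortably covers clean
#'   EEG plus injected artifacts.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 1000) {
  fs <- rec$rate_hz
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- length(rec$channels)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  dig_max <- 32767L
  scale <- dig_max / phys_range
  dig <- round(pmin(pmax(x, -phys_range), phys_range) * scale)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(paste(rec$subject_id, rec$session_id, rec$eye_state), 80)
  wr("placeboeeg synthetic cohort", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (ch in rec$channels) wr(paste("EEG", ch), 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(-phys_range, 8)
  for (i in seq_len(ns)) wr(phys_range, 8)
  for (i in seq_len(ns)) wr(-dig_max, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  # data records: per record, per signal, fs int16 samples
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a plain 16-bit EDF file with a common sampling rate across
#' signals (the format this package writes; most resting-state EEG EDF
#' exports satisfy this).
#'
#' @param path EDF file path.
#' @return An [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                  # version
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)          # prefilter
  nr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nr)) != 1)
    stop("read_edf supports a single common sampling rate only")
  fs <- nr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(nr), size = 2,
                 endian = "little")
  dat <- matrix(0, ns, n_rec * nr[1])
  pos <- 0
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dat[s, ((r - 1) * nr[s] + 1):(r * nr[s])] <-
        raw[(pos + 1):(pos + nr[s])]
      pos <- pos + nr[s]
    }
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offs <- pmin_ - gain * dmin_
  dat <- dat * gain + offs
  channels <- sub("^EEG ", "", labels)
  meta <- strsplit(patient, "\\s+")[[1]]
  subject_id <- if (length(meta) >= 1) meta[1] else "unknown"
  session_id <- if (length(meta) >= 2) meta[2] else "ses1"
  eye_state <- if (length(meta) >= 3 && meta[3] %in% c("EO", "EC"))
    meta[3] else "EO"
  recording(dat, channels, fs, subject_id, session_id, eye_state)
}
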