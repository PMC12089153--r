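# Segmentation: resample to the analysis rate and cut fixed-shape
# overlapping windows, rejecting any window that touches a flagged
# artifact interval.

#' Construct a segment set
#'
#' @param data numeric array `[n_segments x n_channels x n_samples]`.
#' @param index data.frame with one row per segment: `subject_id`,
#'   `session_id`, `eye_state`, `start_s`.
#' @param kept logical vector, one flag per segment.
#' @param reject_reason list of character vectors (rule ids), one per
#'   segment; empty for kept segments.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(data, index, kept, reject_reason) {
  stopifnot(length(dim(data)) == 3, nrow(index) == dim(data)[1],
            length(kept) == dim(data)[1],
            length(reject_reason) == dim(data)[1])
  if (any(kept & vapply(reject_reason, length, 1L) > 0))
    stop("kept segments must have no rejection reason")
  structure(list(data = data, index = index, kept = kept,
                 reject_reason = reject_reason), class = "segment_set")
}

#' @exportS3Method base::print
print.segment_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<segment_set> %d segments [%d x %d], %d kept (%.0f%%)\n",
              d[1], d[2], d[3], sum(x$kept),
              if (d[1]) 100 * mean(x$kept) else 0))
  invisible(x)
}

#' Number of segments in a segment set
#' @param ss a [segment_set()].
#' @return Integer segment count (kept and rejected).
#' @export
n_segments <- function(ss) dim(ss$data)[1]

resample_to <- function(x, from_hz, to_hz) {
  if (abs(from_hz - to_hz) < 1e-9) return(x)
  # rational polyphase FIR resampling via signal::resample
  r <- to_hz / from_hz
  fr <- as.integer(c(1, 2, 4, 5, 8, 10))
  p <- q <- NA
  for (den in 1:64) {
    num <- r * den
    if (abs(num - round(num)) < 1e-9) { p <- round(num); q <- den; break }
  }
  if (is.na(p)) stop("resampling ratio ", r, " is not rational enough")
  as.numeric(signal::resample(x, p, q))
}

#' Cut a recording into fixed-shape segments
#'
#' Resamples to `target_rate` (default 125 Hz) and cuts 16-s half-open
#' windows `[start, start + 16)` starting at every integer second, i.e.
#' with 15 s overlap between consecutive windows. Each window overlapping
#' any artifact interval of `report` is marked rejected with the rule ids
#' involved. Kept segments have exactly
#' `16 * target_rate = 2000` samples per channel.
#'
#' @param rec a filtered [recording()] on the canonical montage.
#' @param report artifact report from [detect_artifacts()] (may be empty).
#' @param target_rate analysis sampling rate in Hz.
#' @param win_s window length in seconds.
#' @param stride_s window stride in seconds.
#' @return A [segment_set()]. If the recording is shorter than `win_s` the
#'   set is empty and a warning is raised.
#' @export
segment_recording <- function(rec, report = NULL, target_rate = 125,
                              win_s = 16, stride_s = 1) {
  dur <- rec_duration(rec)
  nch <- nrow(rec$data)
  wlen <- round(win_s * target_rate)
  if (dur < win_s) {
    warning("recording of ", dur, " s is shorter than the ", win_s,
            " s window; returning an empty segment set")
    return(segment_set(array(0, c(0, nch, wlen)),
                       data.frame(subject_id = character(0),
                                  session_id = character(0),
                                  eye_state = character(0),
                                  start_s = numeric(0)),
                       logical(0), list()))
  }
  y <- t(apply(rec$data, 1, resample_to, from_hz = rec$rate_hz,
               to_hz = target_rate))
  starts <- seq(0, floor(dur - win_s), by = stride_s)
  n_seg <- length(starts)
  data <- array(0, c(n_seg, nch, wlen))
  reasons <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    i0 <- round(starts[i] * target_rate)
    data[i, , ] <- y[, (i0 + 1):(i0 + wlen)]
    if (!is.null(report) && nrow(report)) {
      hit <- report$start_s < starts[i] + win_s & report$end_s > starts[i]
      reasons[[i]] <- unique(report$rule[hit])
    } else reasons[[i]] <- character(0)
  }
  kept <- vapply(reasons, length, 1L) == 0
  idx <- data.frame(subject_id = rec$subject_id,
                    session_id = rec$session_id,
                    eye_state = rec$eye_state,
                    start_s = starts, stringsAsFactors = FALSE)
  segment_set(data, idx, kept, reasons)
}

#' Concatenate segment sets
#'
#' @param sets list of [segment_set()] objects with identical channel and
#'   sample dimensions.
#' @return One combined `segment_set`.
#' @export
bind_segment_sets <- function(sets) {
  sets <- sets[vapply(sets, n_segments, 1L) > 0]
  if (!length(sets)) stop("no non-empty segment sets to bind")
  d <- dim(sets[[1]]$data)
  total <- sum(vapply(sets, n_segments, 1L))
  data <- array(0, c(total, d[2], d[3]))
  at <- 1
  for (s in sets) {
    n <- n_segments(s)
    data[at:(at + n - 1), , ] <- s$data
    at <- at + n
  }
  segment_set(data,
              do.call(rbind, lapply(sets, `[[`, "index")),
              unlist(lapply(sets, `[[`, "kept")),
              do.call(c, lapply(sets, `[[`, "reject_reason")))
}

#' Write / read a segment set on disk
#'
#' The tensor goes into a binary array container (`segments.rds`) and the
#' per-segment bookkeeping into a human-readable TSV sidecar
#' (`index.tsv`: subject, session, eye state, start time, kept flag and
#' comma-joined rejection rules).
#'
#' @param ss a [segment_set()].
#' @param dir output directory (created if needed).
#' @return `dir` (write) or the restored [segment_set()] (read).
#' @export
write_segments <- function(ss, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ss$data, file.path(dir, "segments.rds"))
  side <- cbind(ss$index, kept = ss$kept,
                reject_reason = vapply(ss$reject_reason, paste,
                                       "", collapse = ","))
  write.table(side, file.path(dir, "index.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_segments
#' @export
read_segments <- function(dir) {
  data <- readRDS(file.path(dir, "segments.rds"))
  side <- read.delim(file.path(dir, "index.tsv"),
                     stringsAsFactors = FALSE)
  side$reject_reason[is.na(side$reject_reason)] <- ""
  reasons <- lapply(strsplit(side$reject_reason, ","), function(v)
    v[nzchar(v)])
  segment_set(data,
              side[, c("subject_id", "session_id", "eye_state",
                       "start_s")],
              as.logical(side$kept), reasons)
}

#' Preprocess one recording end to end
#'
#' Canonical-montage mapping, band-pass/notch filtering, ocular
#' correction, artifact detection at the native rate, and segmentation at
#' the analysis rate.
#'
#' @param rec a raw [recording()].
#' @param montage_table optional channel conversion table for
#'   [map_montage()].
#' @param ocular_method passed to [ocular_correct()].
#' @param cfg artifact thresholds from [artifact_config()].
#' @param target_rate,win_s,stride_s segmentation parameters, see
#'   [segment_recording()].
#' @return list with `segments` (a [segment_set()]) and `report` (the
#'   artifact report).
#' @export
preprocess_recording <- function(rec, montage_table = NULL,
                                 ocular_method = "regression",
                                 cfg = artifact_config(),
                                 target_rate = 125, win_s = 16,
                                 stride_s = 1) {
  rec <- map_montage(rec, montage_table)
  rec <- bandpass_notch(rec)
  rec <- ocular_correct(rec, ocular_method)
  report <- detect_artifacts(rec, cfg)
  list(segments = segment_recording(rec, report, target_rate, win_s,
                                    stride_s),
       report = report)
}

#' Preprocess a whole cohort
#'
#' Applies [preprocess_recording()] to every recording and binds the
#' results into one [segment_set()].
#'
#' @param recordings list of [recording()] objects.
#' @param ... passed to [preprocess_recording()].
#' @return A combined [segment_set()].
#' @export
preprocess_cohort <- function(recordings, ...) {
  bind_segment_sets(lapply(recordings, function(r)
    preprocess_recording(r, ...)$segments))
}
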