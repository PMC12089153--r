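#' Canonical 19-channel 10-20 montage
#'
#' Ordered electrode names used throughout the pipeline. Every recording is
#' mapped onto this list before segmentation so that segment tensors always
#' have the same channel axis.
#'
#' @return Character vector of 19 electrode names.
#' @export
canonical_channels <- function() {
  c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz", "T7", "T8",
    "C3", "C4", "Cz", "P7", "P8", "P3", "P4", "Pz", "O1", "O2")
}

#' Construct an EEG recording
#'
#' A recording is one subject/session multichannel resting-state EEG time
#' series with montage information and an eye-state tag.
#'
#' @param data numeric matrix `[n_channels x n_samples]`, amplitudes in
#'   microvolts.
#' @param channels character vector of electrode names, one per row of
#'   `data`; must be unique.
#' @param rate_hz sampling rate in Hz.
#' @param subject_id,session_id identifiers.
#' @param eye_state `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, channels, rate_hz, subject_id = "s01",
                      session_id = "ses1", eye_state = c("EO", "EC")) {
  eye_state <- match.arg(eye_state)
  data <- as.matrix(data)
  if (anyDuplicated(channels))
    stop("channel names must be unique")
  if (nrow(data) != length(channels))
    stop("data has ", nrow(data), " rows but ", length(channels),
         " channel names were given")
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop("rate_hz must be a positive number")
  rownames(data) <- channels
  structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         eye_state = eye_state,
         rate_hz = as.numeric(rate_hz),
         channels = as.character(channels),
         data = data),
    class = "eeg_recording")
}

#' @exportS3Method base::print
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject=%s session=%s eye_state=%s\n",
              x$subject_id, x$session_id, x$eye_state))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$data) / rec$rate_hz

#' Map a recording onto the canonical 10-20 montage
#'
#' Renames channels through a user-supplied conversion table (for example a
#' high-density-net-to-10-20 substitution table), drops unmapped channels
#' and reorders rows into the canonical 19-channel order.
#'
#' @param rec an [recording()].
#' @param table named character vector mapping source channel names to
#'   10-20 names, e.g. `c(E22 = "Fp1", ...)`. Defaults to the identity
#'   mapping on the canonical names.
#' @return An `eeg_recording` whose channels are exactly
#'   [canonical_channels()] in order.
#' @export
map_montage <- function(rec, table = NULL) {
  target <- canonical_channels()
  if (is.null(table))
    table <- setNames(target, target)
  src <- names(table)
  keep <- src[src %in% rec$channels & table %in% target]
  mapped <- setNames(as.character(table[keep]), keep)
  missing <- setdiff(target, unname(mapped))
  if (length(missing))
    stop("montage table does not cover target channel(s): ",
         paste(missing, collapse = ", "))
  # invert: for each target name pick its source row
  src_for <- setNames(names(mapped), unname(mapped))
  out <- rec$data[src_for[target], , drop = FALSE]
  rownames(out) <- target
  rec$data <- out
  rec$channels <- target
  rec
}
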