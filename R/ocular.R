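# Ocular (blink) correction.
#
# The regression method builds a virtual electro-oculogram from the
# low-passed frontal average, masks it to detected blink events, and
# subtracts the least-squares projection of every channel onto that
# regressor. ICA is treated as a pluggable backend: when no backend is
# supplied (or the recording is too short to decompose reliably) the
# method falls back to regression with a warning.

frontal_veog <- function(rec, lp_hz = 4) {
  fp <- match(c("Fp1", "Fp2"), rec$channels)
  if (any(is.na(fp)))
    stop("ocular correction requires at least the Fp1/Fp2 frontal channels")
  v <- colMeans(rec$data[fp, , drop = FALSE])
  lp <- signal::butter(4, lp_hz / (rec$rate_hz / 2), type = "low")
  as.numeric(signal::filtfilt(lp, v))
}

# indices of local maxima of v above thr, at least min_sep samples apart
find_peaks <- function(v, thr, min_sep) {
  cand <- which(v > thr)
  cand <- cand[cand > 1 & cand < length(v)]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] >= v[cand + 1]]
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  last <- -Inf
  for (i in cand[order(-v[cand])]) {
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

detect_blink_peaks <- function(rec, k = 4) {
  v <- frontal_veog(rec)
  s <- mad(v)
  if (s <= 0) return(list(v = v, peaks = integer(0)))
  list(v = v, peaks = find_peaks(v, k * s, round(0.25 * rec$rate_hz)))
}

#' Remove blink activity from a recording
#'
#' @param rec a filtered [recording()].
#' @param method `"regression"` (virtual-EOG regression, the default),
#'   `"ica"` (delegates to `ica_fun`; falls back to regression when absent
#'   or when the recording is shorter than 60 s), or `"none"` (identity).
#' @param blink_k blink detection threshold in robust SDs of the low-passed
#'   frontal average.
#' @param ica_fun optional function `(rec) -> rec` implementing an
#'   ICA-based correction.
#' @return The corrected recording.
#' @export
ocular_correct <- function(rec, method = c("regression", "ica", "none"),
                           blink_k = 4, ica_fun = NULL) {
  method <- match.arg(method)
  if (method == "none") return(rec)
  if (method == "ica") {
    if (rec_duration(rec) < 60) {
      warning("recording shorter than 60 s: ICA would be unreliable, ",
              "falling back to regression-based ocular correction")
    } else if (is.null(ica_fun)) {
      warning("no ICA backend supplied; falling back to regression-based ",
              "ocular correction")
    } else {
      return(ica_fun(rec))
    }
  }
  det <- detect_blink_peaks(rec, blink_k)
  if (!length(det$peaks)) return(rec)
  # regressor: virtual EOG restricted to blink neighbourhoods
  fs <- rec$rate_hz
  mask <- rep(0, length(det$v))
  half <- round(0.4 * fs)
  for (p in det$peaks) {
    lo <- max(1, p - half); hi <- min(length(mask), p + half)
    mask[lo:hi] <- 1
  }
  r <- det$v * mask
  denom <- sum(r^2)
  beta <- as.numeric(rec$data %*% r) / denom
  rec$data <- rec$data - outer(beta, r)
  rownames(rec$data) <- rec$channels
  rec
}
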