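# Filtering and spectral primitives. IIR designs come from the `signal`
# package; all filters are applied forward-backward (zero phase).

filtfilt_mat <- function(filt, x) {
  t(apply(x, 1, function(row) signal::filtfilt(filt, row)))
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase 0.5-100 Hz band-pass (Butterworth, realized as a 2nd-order
#' high-pass plus 2nd-order low-pass cascade for numerical stability at the
#' very low normalized corner frequency) followed by 2nd-order notch stops
#' at 50 and 60 Hz. Filtering precedes resampling, so the sampling rate
#' must keep 100 Hz below Nyquist.
#'
#' @param rec a [recording()].
#' @param band pass band in Hz.
#' @param notches centre frequencies of the notch stops, in Hz.
#' @param notch_halfwidth half width of each notch stop band, in Hz.
#' @return The filtered recording.
#' @export
bandpass_notch <- function(rec, band = c(0.5, 100), notches = c(50, 60),
                           notch_halfwidth = 2) {
  nyq <- rec$rate_hz / 2
  if (band[2] >= nyq)
    stop("sampling rate ", rec$rate_hz, " Hz is too low for a ", band[2],
         " Hz pass band; filtering precedes resampling and cannot be ",
         "deferred to the resampled signal")
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(2, band[2] / nyq, type = "low")
  x <- filtfilt_mat(hp, rec$data)
  x <- filtfilt_mat(lp, x)
  for (f0 in notches) {
    if (f0 + notch_halfwidth >= nyq) next
    bs <- signal::butter(1, c(f0 - notch_halfwidth, f0 + notch_halfwidth) /
                           nyq, type = "stop")
    x <- filtfilt_mat(bs, x)
  }
  rownames(x) <- rec$channels
  rec$data <- x
  rec
}

#' Welch power spectral density
#'
#' One-sided Welch PSD estimate with Hann windows (default 4 s, 50%
#' overlap), per-window demeaning, in units of power per Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg window length in samples (clipped to `length(x)`).
#' @param overlap fractional window overlap.
#' @return list with `freq` (Hz) and `psd` (power/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = round(4 * fs), overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nperseg - 1)]
    (seg - mean(seg)) * w
  }, numeric(nperseg))
  spec <- mvfft(segs)
  nf <- floor(nperseg / 2) + 1
  p <- rowMeans(Mod(spec[seq_len(nf), , drop = FALSE])^2)
  scale <- 1 / (fs * sum(w^2))
  p <- p * scale
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = p * dbl)
}

band_power_psd <- function(freq, psd, lo, hi) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= lo & freq < hi]) * df
}

#' Band power of a single trace
#'
#' Welch-estimated total power in `[lo, hi)` Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz.
#' @param nperseg Welch window length in samples.
#' @return Power in squared input units.
#' @export
band_power_vec <- function(x, fs, lo, hi, nperseg = round(4 * fs)) {
  ps <- welch_psd(x, fs, nperseg = nperseg)
  band_power_psd(ps$freq, ps$psd, lo, hi)
}
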