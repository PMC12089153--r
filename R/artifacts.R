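# Rule-based artifact detection.
#
# Six independent rules, each evaluated on its own statistic:
#   muscle            robust z of log 75-95 Hz band power, 1-s windows
#   extreme_voltage   any |sample| > 200 uV (sample level)
#   abrupt_transition baseline jump: difference of adjacent 0.5-s window
#                     means, thresholded in recording SDs
#   kurtosis          robust z of per-window sample kurtosis > 4
#   blink             >= 3 frontal positive transients above 4 robust SDs
#                     of the low-passed frontal average within a 16-s span
#   bridging          variance of a channel-pair difference below 0.5 uV^2,
#                     whole recording
#
# Robust z-scores (median / MAD across windows) keep the per-window rules
# calibrated: with plain mean/SD scoring a clean recording of ~100 windows
# x 19 channels would be expected to throw several false flags.

#' Artifact detection thresholds
#'
#' @param muscle_z robust z threshold on log 75-95 Hz window power.
#' @param voltage_uv absolute amplitude threshold in microvolts.
#' @param abrupt_sd baseline-jump threshold in recording standard
#'   deviations.
#' @param kurtosis_z z threshold on window kurtosis (pooled over channels
#'   and windows).
#' @param kurtosis_floor absolute kurtosis a window must additionally
#'   exceed (Gaussian data sit at 3); guards against the heavy right tail
#'   that oscillator envelopes give the kurtosis estimator.
#' @param kurtosis_win_s kurtosis window length in seconds.
#' @param blink_k blink peak threshold in robust SDs of the low-passed
#'   frontal average.
#' @param blink_count minimum number of blink peaks within a 16-s span for
#'   the "persistent blinks" rule to fire.
#' @param bridge_var channel-pair difference variance below which a pair
#'   counts as bridged, in microvolts squared.
#' @param rules subset of [artifact_rules()] to evaluate.
#' @return A list of thresholds for [detect_artifacts()].
#' @export
artifact_config <- function(muscle_z = 5, voltage_uv = 200, abrupt_sd = 4,
                            kurtosis_z = 4, kurtosis_floor = 7,
                            kurtosis_win_s = 1, blink_k = 4,
                            blink_count = 3, bridge_var = 0.5,
                            rules = artifact_rules()) {
  stopifnot(all(rules %in% artifact_rules()))
  list(muscle_z = muscle_z, voltage_uv = voltage_uv, abrupt_sd = abrupt_sd,
       kurtosis_z = kurtosis_z, kurtosis_floor = kurtosis_floor,
       kurtosis_win_s = kurtosis_win_s, blink_k = blink_k,
       blink_count = blink_count, bridge_var = bridge_var, rules = rules)
}

robust_z <- function(x) {
  m <- median(x)
  s <- mad(x)
  if (!is.finite(s) || s <= 0) s <- sd(x)
  if (!is.finite(s) || s <= 0) return(rep(0, length(x)))
  (x - m) / s
}

report_row <- function(start_s, end_s, rule, channel, score) {
  data.frame(start_s = start_s, end_s = end_s, rule = rule,
             channel = if (is.null(channel)) NA_character_ else channel,
             score = score, stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             rule = character(0), channel = character(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Detect artifacts in a filtered recording
#'
#' Evaluates the six rejection rules independently and returns one report
#' entry per flagged window per rule. An empty report is valid (clean
#' recording). Timestamps are in seconds so that downstream rejection is
#' independent of the sampling rate.
#'
#' @param rec a band-pass filtered [recording()].
#' @param cfg thresholds from [artifact_config()].
#' @return data.frame with columns `start_s`, `end_s`, `rule`, `channel`,
#'   `score`.
#' @export
detect_artifacts <- function(rec, cfg = artifact_config()) {
  fs <- rec$rate_hz
  dur <- rec_duration(rec)
  n_win <- floor(dur)
  out <- list(empty_report())
  win_of <- function(ch_rows) ch_rows   # readability only

  per_window_stat <- function(x, fun) {
    vapply(seq_len(n_win), function(w) {
      fun(x[((w - 1) * fs + 1):(w * fs)])
    }, numeric(1))
  }

  if ("muscle" %in% cfg$rules) {
    for (ci in seq_len(nrow(rec$data))) {
      x <- rec$data[ci, ]
      lp <- per_window_stat(x, function(seg) {
        sp <- Mod(fft(seg))^2
        f <- (seq_along(seg) - 1) * fs / length(seg)
        log(sum(sp[f >= 75 & f <= 95]) + 1e-12)
      })
      z <- robust_z(lp)
      for (w in which(z > cfg$muscle_z))
        out[[length(out) + 1]] <- report_row(w - 1, w, "muscle",
                                             rec$channels[ci], z[w])
    }
  }

  if ("kurtosis" %in% cfg$rules) {
    kw <- round(cfg$kurtosis_win_s * fs)
    n_kwin <- floor(ncol(rec$data) / kw)
    if (n_kwin >= 2) {
      ku <- matrix(0, nrow(rec$data), n_kwin)
      for (ci in seq_len(nrow(rec$data))) {
        x <- rec$data[ci, ]
        ku[ci, ] <- vapply(seq_len(n_kwin), function(w) {
          seg <- x[((w - 1) * kw + 1):(w * kw)]
          m <- mean(seg); v <- mean((seg - m)^2)
          if (v <= 0) return(3)
          mean((seg - m)^4) / v^2
        }, numeric(1))
      }
      # z pooled over channels x windows (plain mean/SD: the estimator is
      # right-skewed on oscillatory EEG and a MAD scale would over-flag);
      # the absolute floor keeps envelope outliers of genuinely Gaussian
      # amplitude distributions from firing the rule
      z <- (ku - mean(ku)) / max(sd(ku), .Machine$double.eps)
      hits <- which(z > cfg$kurtosis_z & ku > cfg$kurtosis_floor,
                    arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        ci <- hits[r, 1]; w <- hits[r, 2]
        out[[length(out) + 1]] <- report_row(
          (w - 1) * cfg$kurtosis_win_s,
          min(dur, w * cfg$kurtosis_win_s), "kurtosis",
          rec$channels[ci], z[ci, w])
      }
    }
  }

  if ("extreme_voltage" %in% cfg$rules) {
    for (ci in seq_len(nrow(rec$data))) {
      x <- abs(rec$data[ci, ])
      mx <- per_window_stat(x, max)
      for (w in which(mx > cfg$voltage_uv))
        out[[length(out) + 1]] <- report_row(w - 1, w, "extreme_voltage",
                                             rec$channels[ci], mx[w])
    }
  }

  if ("abrupt_transition" %in% cfg$rules) {
    half <- round(fs / 2)
    n_half <- floor(ncol(rec$data) / half)
    for (ci in seq_len(nrow(rec$data))) {
      x <- rec$data[ci, ]
      m <- vapply(seq_len(n_half), function(j)
        mean(x[((j - 1) * half + 1):(j * half)]), numeric(1))
      jump <- abs(diff(m))
      thr <- cfg$abrupt_sd * sd(x)
      for (j in which(jump > thr)) {
        t_b <- j * 0.5                   # boundary instant in seconds
        out[[length(out) + 1]] <- report_row(
          max(0, t_b - 0.5), min(dur, t_b + 0.5), "abrupt_transition",
          rec$channels[ci], jump[j] / sd(x))
      }
    }
  }

  if ("blink" %in% cfg$rules) {
    det <- detect_blink_peaks(rec, cfg$blink_k)
    if (length(det$peaks)) {
      t_p <- det$peaks / fs
      persistent <- vapply(t_p, function(t0)
        sum(abs(t_p - t0) <= 8) >= cfg$blink_count, logical(1))
      for (t0 in t_p[persistent])
        out[[length(out) + 1]] <- report_row(max(0, t0 - 0.5),
                                             min(dur, t0 + 0.5),
                                             "blink", NULL, NA_real_)
    }
  }

  if ("bridging" %in% cfg$rules) {
    cc <- stats::cov(t(rec$data))
    v <- diag(cc)
    nch <- nrow(rec$data)
    for (i in seq_len(nch - 1)) {
      for (j in (i + 1):nch) {
        dv <- v[i] + v[j] - 2 * cc[i, j]
        if (dv < cfg$bridge_var)
          out[[length(out) + 1]] <- report_row(
            0, dur, "bridging",
            paste(rec$channels[i], rec$channels[j], sep = "|"), dv)
      }
    }
  }

  do.call(rbind, out)
}
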