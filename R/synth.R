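# Synthetic EEG cohort generator.
#
# The signal model is a sum of 1/f^chi Gaussian background noise (chi ~ 1),
# band-limited Gaussian oscillators (theta, alpha, lower/upper beta) with
# per-subject log-normal amplitudes, plus class-dependent amplitude shifts
# at a fixed set of channels. Responder status is drawn from a logistic
# model with sex and age terms; behavioural covariates are Gaussians with a
# configurable correlation to responder status. This reproduces the
# statistical structure the downstream analyses assume (planted spectral
# effects, sex effect, age-score link) without any attempt at realistic
# ERP morphology or volume conduction.

THETA_EFFECT_CHANNELS <- c("Fz", "Cz", "F8", "C3")
BETA_LOW_EFFECT_CHANNELS <- c("F3", "F4")

BAND_DEFS <- list(theta = c(4, 8), alpha = c(8, 13),
                  beta_low = c(13, 20), beta_high = c(20, 30))

#' Specify a synthetic EEG cohort
#'
#' Parameters of the generative model behind [generate_cohort()]. The
#' defaults describe a depression-trial-like resting-state cohort: 2-minute
#' eyes-open and eyes-closed recordings at 250 Hz, a ~40% placebo-response
#' rate, ages uniform on 18-65, males shifted down in responder log-odds,
#' and responder-dependent theta (Fz/Cz/F8/C3) and lower-beta (F3/F4)
#' amplitude shifts.
#'
#' @param n_subjects number of subjects.
#' @param responder_rate baseline probability of responding, in `[0, 1]`.
#' @param sessions_per_subject sessions per eye state (each session yields
#'   one EO and one EC recording).
#' @param duration_s recording duration in seconds (>= 16).
#' @param native_rate_hz sampling rate of the generated raw data.
#' @param effect_theta standardized (log-amplitude z-unit) downward shift of
#'   the theta oscillator amplitude at Fz/Cz/F8/C3 in responders. Positive
#'   values give responders *lower* theta power, matching the negative
#'   association between theta power and predicted response that the
#'   pipeline is designed to recover.
#' @param effect_beta_low same, for the 13-20 Hz oscillator at F3/F4.
#' @param sex_effect additive shift in responder log-odds for males.
#' @param age_slope responder log-odds slope per standard deviation of age
#'   (negative: younger subjects respond more).
#' @param artifact_rates named per-rule probabilities that one artifact of
#'   that class is injected into a recording; names must be a subset of
#'   [artifact_rules()]. Default: no injected artifacts.
#' @param covariates named list of target correlations between generated
#'   Gaussian behavioural covariates and responder status.
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   cohort.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 20, responder_rate = 0.4,
                        sessions_per_subject = 1, duration_s = 120,
                        native_rate_hz = 250,
                        effect_theta = 1, effect_beta_low = 1,
                        sex_effect = -0.5, age_slope = -0.5,
                        artifact_rates = NULL,
                        covariates = list(extraversion = 0.2,
                                          reaction_time = -0.25),
                        seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid cohort spec field '", field, "': ", msg)
  }
  chk(is.numeric(n_subjects) && n_subjects >= 1, "n_subjects",
      "must be a positive integer")
  chk(is.numeric(responder_rate) && responder_rate >= 0 &&
        responder_rate <= 1, "responder_rate", "must lie in [0, 1]")
  chk(is.numeric(sessions_per_subject) && sessions_per_subject >= 1,
      "sessions_per_subject", "must be a positive integer")
  chk(is.numeric(duration_s) && duration_s >= 16, "duration_s",
      "must be at least 16 seconds")
  chk(is.numeric(native_rate_hz) && native_rate_hz > 200, "native_rate_hz",
      "must exceed 200 Hz so the 0.5-100 Hz band is resolvable")
  if (!is.null(artifact_rates)) {
    chk(all(names(artifact_rates) %in% artifact_rules()), "artifact_rates",
        paste("names must be among:", paste(artifact_rules(), collapse = ", ")))
    chk(all(unlist(artifact_rates) >= 0 & unlist(artifact_rates) <= 1),
        "artifact_rates", "probabilities must lie in [0, 1]")
  }
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be one integer")
  structure(list(
    n_subjects = as.integer(n_subjects),
    responder_rate = responder_rate,
    sessions_per_subject = as.integer(sessions_per_subject),
    duration_s = duration_s,
    native_rate_hz = native_rate_hz,
    effect_theta = effect_theta,
    effect_beta_low = effect_beta_low,
    sex_effect = sex_effect,
    age_slope = age_slope,
    artifact_rates = artifact_rates,
    covariates = covariates,
    seed = as.integer(seed)), class = "cohort_spec")
}

# unit-RMS 1/f^chi background noise, one column per channel
pink_noise <- function(n, n_ch, chi = 1) {
  white <- matrix(rnorm(n * n_ch), n, n_ch)
  spec <- mvfft(white)
  f <- c(1, seq_len(n - 1))              # avoid f = 0
  f <- pmin(f, n - f + 1)                # symmetric frequency index
  g <- 1 / f^(chi / 2)
  g[1] <- 0                              # remove DC
  x <- Re(mvfft(spec * g, inverse = TRUE)) / n
  scale(x, center = FALSE, scale = apply(x, 2, sd))
}

# unit-RMS Gaussian noise band-limited to [f_lo, f_hi] Hz
band_noise <- function(n, n_ch, fs, f_lo, f_hi) {
  white <- matrix(rnorm(n * n_ch), n, n_ch)
  spec <- mvfft(white)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  keep <- freq >= f_lo & freq <= f_hi
  spec[!keep, ] <- 0
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  scale(x, center = FALSE, scale = apply(x, 2, sd))
}

# mean oscillator RMS amplitude (microvolts) and across-subject log-normal
# spread; clean total RMS stays in the 10-30 uV range so the 200 uV
# voltage rule only fires on injected events
SYNTH_AMP <- list(mu = c(theta = 4, alpha = 6, beta_low = 3, beta_high = 2),
                  sigma_log = 0.25, alpha_ec_gain = 1.8,
                  background_range = c(8, 14), sensor_noise = 2)

#' Generate cohort metadata only
#'
#' Draws the subject table of [generate_cohort()] (ages, sex, arm,
#' responder status, depression scores, covariates, and the per-subject
#' oscillator amplitude z-scores that the recordings are built from)
#' without synthesising any EEG. Useful when only the statistical structure
#' is needed, e.g. for correlation screening at large n.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per subject; the planted oscillator
#'   z-scores are attached as attribute `"amp_z"`.
#' @export
generate_metadata <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_subjects
    subject_id <- sprintf("sub%03d", seq_len(n))
    age <- runif(n, 18, 65)
    sex <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
    arm <- rep(c("placebo", "drug"), length.out = n)[sample.int(n)]
    z_age <- if (n > 1 && sd(age) > 0) (age - mean(age)) / sd(age)
             else rep(0, n)
    logit <- qlogis(spec$responder_rate) +
      spec$sex_effect * (sex == "male") + spec$age_slope * z_age
    responder <- rbinom(n, 1, plogis(logit)) == 1
    baseline_score <- pmax(14, round(rnorm(n, 18, 3)))
    endpoint_score <- ifelse(responder,
                             sample(2:7, n, replace = TRUE),
                             pmax(8, round(rnorm(n, 14, 4))))
    remission <- endpoint_score <= 7     # HAM-D-17 remission criterion
    meta <- data.frame(subject_id, age_years = age, sex, arm,
                       baseline_score, endpoint_score,
                       responder, remission,
                       stringsAsFactors = FALSE)
    s_resp <- if (n > 1) sd(responder) else 0
    z_resp <- (responder - mean(responder)) /
      max(s_resp, .Machine$double.eps)
    for (nm in names(spec$covariates)) {
      rho <- spec$covariates[[nm]]
      meta[[nm]] <- rho * z_resp + sqrt(max(0, 1 - rho^2)) * rnorm(n)
    }
    # per-subject oscillator amplitude z-scores (19 channels x 4 bands),
    # with the class shift planted at the listed channels
    ch <- canonical_channels()
    amp_z <- array(rnorm(n * 19 * 4), dim = c(n, 19, 4),
                   dimnames = list(subject_id, ch, names(BAND_DEFS)))
    idx_th <- match(THETA_EFFECT_CHANNELS, ch)
    idx_bl <- match(BETA_LOW_EFFECT_CHANNELS, ch)
    amp_z[responder, idx_th, "theta"] <-
      amp_z[responder, idx_th, "theta"] - spec$effect_theta
    amp_z[responder, idx_bl, "beta_low"] <-
      amp_z[responder, idx_bl, "beta_low"] - spec$effect_beta_low
    attr(meta, "amp_z") <- amp_z
    meta
  })
}

synth_recording <- function(spec, subject_id, session_id, eye_state,
                            amp_z_subject, background_rms) {
  fs <- spec$native_rate_hz
  n <- round(spec$duration_s * fs)
  ch <- canonical_channels()
  x <- t(pink_noise(n, 19)) * background_rms
  for (b in names(BAND_DEFS)) {
    amp <- SYNTH_AMP$mu[[b]] * exp(SYNTH_AMP$sigma_log * amp_z_subject[, b])
    if (b == "alpha" && eye_state == "EC")
      amp <- amp * SYNTH_AMP$alpha_ec_gain
    x <- x + t(band_noise(n, 19, fs, BAND_DEFS[[b]][1], BAND_DEFS[[b]][2])) *
      amp
  }
  x <- x + matrix(rnorm(19 * n, sd = SYNTH_AMP$sensor_noise), 19, n)
  recording(x, ch, fs, subject_id, session_id, eye_state)
}

#' Generate a synthetic EEG cohort
#'
#' Produces one eyes-open and one eyes-closed recording per subject per
#' session, plus a consistent metadata table. Responder subjects carry the
#' planted theta and lower-beta amplitude shifts of the spec; eyes-closed
#' sessions carry elevated alpha. If `spec$artifact_rates` is set, each
#' recording independently receives one injected artifact of each named
#' class with the given probability.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `recordings` (list of [recording()]) and
#'   `metadata` (data.frame, one row per subject).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  meta <- generate_metadata(spec)
  amp_z <- attr(meta, "amp_z")
  with_local_seed(spec$seed + 1L, {
    bg <- runif(spec$n_subjects, SYNTH_AMP$background_range[1],
                SYNTH_AMP$background_range[2])
    recs <- list()
    for (i in seq_len(spec$n_subjects)) {
      for (s in seq_len(spec$sessions_per_subject)) {
        for (es in c("EO", "EC")) {
          rec <- synth_recording(spec, meta$subject_id[i],
                                 sprintf("ses%d", s), es,
                                 amp_z[i, , ], bg[i])
          if (!is.null(spec$artifact_rates)) {
            for (rule in names(spec$artifact_rates)) {
              if (runif(1) < spec$artifact_rates[[rule]]) {
                at <- floor(runif(1, 0, spec$duration_s - 4))
                rec <- inject_artifact(rec, rule, at)
              }
            }
          }
          recs[[length(recs) + 1]] <- rec
        }
      }
    }
    list(recordings = recs, metadata = meta)
  })
}

#' Artifact rule identifiers
#'
#' @return Character vector of the six rejection-rule ids.
#' @export
artifact_rules <- function() {
  c("muscle", "extreme_voltage", "abrupt_transition",
    "kurtosis", "blink", "bridging")
}

#' Inject a synthetic artifact into a recording
#'
#' Adds one event of the named artifact class, shaped so that it is caught
#' by exactly its own rejection rule: a 10 Hz burst exceeding 200 uV
#' (extreme_voltage), a 75-95 Hz burst (muscle), a 2-s baseline step
#' (abrupt_transition), a smooth high-kurtosis spike train (kurtosis), a
#' train of frontal positive transients on Fp1/Fp2 (blink), or a duplicated
#' channel pair for the whole recording (bridging).
#'
#' @param rec a [recording()].
#' @param rule one of [artifact_rules()].
#' @param at_s event onset in seconds (ignored for `bridging`).
#' @param channel target channel (defaults: `C4` for single-channel events,
#'   `P3`/`P4` for bridging).
#' @return A modified copy of `rec`.
#' @export
inject_artifact <- function(rec, rule, at_s = 0, channel = NULL) {
  if (!rule %in% artifact_rules())
    stop("unknown artifact rule '", rule, "'; valid rules: ",
         paste(artifact_rules(), collapse = ", "))
  fs <- rec$rate_hz
  dur <- rec_duration(rec)
  ev_dur <- switch(rule, abrupt_transition = 2, blink = 5, bridging = 0, 1)
  if (rule != "bridging" && at_s + ev_dur > dur)
    stop("artifact at ", at_s, " s (+", ev_dur, " s) exceeds recording ",
         "duration ", dur, " s")
  idx <- function(t0, t1) (round(t0 * fs) + 1):min(round(t1 * fs), ncol(rec$data))
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
  ch <- if (is.null(channel)) "C4" else channel
  ci <- match(ch, rec$channels)
  if (rule != "blink" && rule != "bridging" && is.na(ci))
    stop("channel '", ch, "' not present")

  # flat-top (Tukey) envelope: a tapered-but-sustained burst keeps a 1-s
  # window's amplitude distribution close to that of a stationary signal,
  # so burst-type fixtures do not leak into the kurtosis rule
  tukey <- function(n, frac = 0.15) {
    taper <- round(frac * n)
    c(hann(2 * taper)[1:taper], rep(1, n - 2 * taper),
      hann(2 * taper)[(taper + 1):(2 * taper)])
  }

  if (rule == "extreme_voltage") {
    ii <- idx(at_s, at_s + 1)
    t <- seq_along(ii) / fs
    rec$data[ci, ii] <- rec$data[ci, ii] +
      250 * sin(2 * pi * 10 * t) * tukey(length(ii))
  } else if (rule == "muscle") {
    ii <- idx(at_s, at_s + 1)
    n <- length(ii)
    burst <- band_noise(n, 1, fs, 75, 95)[, 1] * tukey(n)
    burst <- burst / sd(burst) * 25
    rec$data[ci, ii] <- rec$data[ci, ii] + burst
  } else if (rule == "abrupt_transition") {
    ii <- idx(at_s, at_s + 2)
    rec$data[ci, ii] <- rec$data[ci, ii] + 150
  } else if (rule == "kurtosis") {
    ii <- idx(at_s, at_s + 1)
    n <- length(ii)
    spike_t <- round(seq(0.15, 0.85, length.out = 4) * n)
    sgn <- c(1, -1, 1, -1)
    tgrid <- seq_len(n)
    add <- rep(0, n)
    for (k in seq_along(spike_t))
      add <- add + sgn[k] * 150 * exp(-(tgrid - spike_t[k])^2 /
                                        (2 * (0.004 * fs)^2))
    rec$data[ci, ii] <- rec$data[ci, ii] + add
  } else if (rule == "blink") {
    fp <- match(c("Fp1", "Fp2"), rec$channels)
    if (any(is.na(fp))) stop("blink injection requires Fp1 and Fp2")
    w <- round(0.3 * fs)
    for (k in 0:4) {
      ii <- idx(at_s + k, at_s + k + 0.3)
      bump <- 100 * hann(length(ii))
      rec$data[fp[1], ii] <- rec$data[fp[1], ii] + bump
      rec$data[fp[2], ii] <- rec$data[fp[2], ii] + 0.9 * bump
    }
  } else if (rule == "bridging") {
    pair <- if (is.null(channel)) c("P3", "P4") else channel
    if (length(pair) != 2) stop("bridging needs a channel pair")
    pi_ <- match(pair, rec$channels)
    if (any(is.na(pi_))) stop("bridging channels not present")
    rec$data[pi_[2], ] <- rec$data[pi_[1], ] +
      rnorm(ncol(rec$data), sd = 0.2)
  }
  rec
}

#' Write a cohort to disk
#'
#' One EDF file per recording (named
#' `<subject>_<session>_<eyestate>.edf`) plus `metadata.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    f <- sprintf("%s_%s_%s.edf", rec$subject_id, rec$session_id,
                 rec$eye_state)
    write_edf(rec, file.path(dir, f))
  }
  meta <- cohort$metadata
  attr(meta, "amp_z") <- NULL
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `*.edf` files and `metadata.csv`.
#' @return list with `recordings` and `metadata`, as [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE))
  recs <- lapply(files, read_edf)
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  list(recordings = recs, metadata = meta)
}
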