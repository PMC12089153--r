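# Band power and the bootstrapped mixed-effects regression of prediction
# scores on per-channel spectral power.

#' Frequency band definitions
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, lower beta 13-20 Hz, upper beta 20-30 Hz.
#'
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
band_definitions <- function() BAND_DEFS

#' Absolute band power per session, channel and band
#'
#' Welch PSD (4-s Hann windows, 50% overlap) per channel of every kept
#' segment, integrated over each band; the session-level value is the
#' mean over that session's kept segments. Power is absolute, in
#' microvolts squared.
#'
#' @param segments a [segment_set()] (data at `rate_hz`).
#' @param rate_hz sampling rate of the segment data.
#' @param bands named list of band edges, as [band_definitions()].
#' @return data.frame: `subject_id`, `session_id`, `eye_state`,
#'   `channel`, `band`, `power`.
#' @export
band_power_table <- function(segments, rate_hz = 125,
                             bands = band_definitions()) {
  for (b in names(bands))
    if (bands[[b]][2] > rate_hz / 2)
      stop("band '", b, "' extends above the Nyquist frequency ",
           rate_hz / 2, " Hz")
  kept <- which(segments$kept)
  if (!length(kept)) stop("no kept segments")
  idx <- segments$index[kept, , drop = FALSE]
  ses_key <- paste(idx$subject_id, idx$session_id, idx$eye_state,
                   sep = "\r")
  channels <- canonical_channels()
  nper <- round(4 * rate_hz)
  out <- list()
  for (sk in unique(ses_key)) {
    rows <- kept[ses_key == sk]
    meta <- idx[match(sk, ses_key), ]
    # mean band power over segments
    acc <- matrix(0, length(channels), length(bands),
                  dimnames = list(channels, names(bands)))
    for (r in rows) {
      for (ci in seq_along(channels)) {
        ps <- welch_psd(segments$data[r, ci, ], rate_hz, nperseg = nper)
        for (b in names(bands))
          acc[ci, b] <- acc[ci, b] +
            band_power_psd(ps$freq, ps$psd, bands[[b]][1], bands[[b]][2])
      }
    }
    acc <- acc / length(rows)
    out[[sk]] <- data.frame(
      subject_id = meta$subject_id, session_id = meta$session_id,
      eye_state = meta$eye_state,
      channel = rep(channels, times = length(bands)),
      band = rep(names(bands), each = length(channels)),
      power = as.vector(acc), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Session-level prediction scores
#'
#' Averages a prediction table over models and segments within each
#' (subject, session, eye state); the response variable of the spectral
#' regression.
#'
#' @param preds prediction table (see [aggregate_subject_scores()]).
#' @return data.frame: `subject_id`, `session_id`, `eye_state`, `score`.
#' @export
session_scores <- function(preds) {
  k <- pred_keys(preds)
  seg <- tapply(preds$probability, k$seg, mean)
  first <- match(names(seg), k$seg)
  ses_key <- k$ses[first]
  sc <- tapply(as.numeric(seg), ses_key, mean)
  parts <- do.call(rbind, strsplit(names(sc), "\r", fixed = TRUE))
  data.frame(subject_id = parts[, 1], session_id = parts[, 2],
             eye_state = parts[, 3], score = as.numeric(sc),
             stringsAsFactors = FALSE)
}

#' Mixed-effects regression of prediction on one spectral predictor
#'
#' Fits `score ~ power_z + sex * eye_state + (1 | subject)` where
#' `power_z` is the selected (channel, band) power, z-scored across the
#' rows of the fitting data so that coefficients are comparable across
#' predictors.
#'
#' @param data data.frame with columns `score`, `power`, `sex`,
#'   `eye_state`, `subject_id`.
#' @return list: `coef` (power_z fixed effect), `fixed` (all fixed
#'   effects), `singular` flag.
#' @export
fit_mixed_model <- function(data) {
  s <- sd(data$power)
  data$power_z <- if (is.finite(s) && s > 0)
    (data$power - mean(data$power)) / s else data$power * 0
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(score ~ power_z + sex * eye_state + (1 | subject_id),
               data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular =
                                             lme4::.makeCC("ignore",
                                                           tol = 1e-4)))))
  fe <- lme4::fixef(fit)
  list(coef = unname(fe["power_z"]), fixed = fe,
       singular = lme4::isSingular(fit))
}

#' Simulate session scores with a planted power coefficient
#'
#' Calibration utility for the bootstrapped regression: generates
#' per-(subject, session) band power (log-normal) and prediction scores
#' from the same mixed model the regression fits, with a known
#' standardized power coefficient. Used to verify parameter recovery and
#' type-I calibration.
#'
#' @param n_subjects participants (two sessions each: EO and EC).
#' @param coef true standardized power coefficient.
#' @param sex_beta,eye_beta,interaction_beta fixed effects of sex, eye
#'   state and their interaction on the score.
#' @param subject_sd random-intercept SD.
#' @param resid_sd residual SD.
#' @param channel,band predictor labels stamped on the power table.
#' @param seed RNG seed.
#' @return list with `scores`, `powers`, `meta` ready for
#'   [bootstrap_regression()].
#' @export
simulate_prediction_power_data <- function(n_subjects = 200, coef = -0.1,
                                           sex_beta = -0.05,
                                           eye_beta = 0.02,
                                           interaction_beta = 0.01,
                                           subject_sd = 0.08,
                                           resid_sd = 0.08,
                                           channel = "Fz", band = "theta",
                                           seed = 1) {
  with_local_seed(seed, {
    subject_id <- sprintf("sub%03d", seq_len(n_subjects))
    sex <- ifelse(rbinom(n_subjects, 1, 0.5) == 1, "male", "female")
    u <- rnorm(n_subjects, sd = subject_sd)
    rows <- expand.grid(subject_id = subject_id,
                        eye_state = c("EO", "EC"),
                        stringsAsFactors = FALSE)
    rows$session_id <- "ses1"
    i <- match(rows$subject_id, subject_id)
    rows$power <- exp(rnorm(nrow(rows), mean = 2, sd = 0.5))
    z <- (rows$power - mean(rows$power)) / sd(rows$power)
    male <- as.numeric(sex[i] == "male")
    ec <- as.numeric(rows$eye_state == "EC")
    rows$score <- 0.5 + coef * z + sex_beta * male + eye_beta * ec +
      interaction_beta * male * ec + u[i] + rnorm(nrow(rows), sd = resid_sd)
    list(scores = rows[, c("subject_id", "session_id", "eye_state",
                           "score")],
         powers = data.frame(rows[, c("subject_id", "session_id",
                                      "eye_state")],
                             channel = channel, band = band,
                             power = rows$power,
                             stringsAsFactors = FALSE),
         meta = data.frame(subject_id = subject_id, sex = sex,
                           stringsAsFactors = FALSE))
  })
}

# fast path for the bootstrap loop: identical model to fit_mixed_model
# but through lme4's modular interface, skipping the merMod wrap-up
fast_lmm_coef <- function(data) {
  s <- sd(data$power)
  data$power_z <- if (is.finite(s) && s > 0)
    (data$power - mean(data$power)) / s else data$power * 0
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular =
                              lme4::.makeCC("ignore", tol = 1e-4))
  lf <- suppressMessages(suppressWarnings(
    lme4::lFormula(score ~ power_z + sex * eye_state + (1 | subject_id),
                   data = data, REML = FALSE, control = ctrl)))
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  opt <- suppressMessages(suppressWarnings(lme4::optimizeLmer(devfun)))
  beta <- environment(devfun)$pp$beta(1)
  names(beta) <- colnames(lf$X)
  list(coef = unname(beta["power_z"]), singular = any(opt$par < 1e-4))
}

#' Bootstrapped spectral regression
#'
#' For each requested (channel, band) predictor, resamples participants
#' with replacement (all sessions of a drawn participant travel together;
#' duplicated participants are re-labelled so the random intercept treats
#' them as distinct), refits the mixed model on each bootstrap sample,
#' and summarizes the coefficient distribution. An effect is significant
#' when the two-tailed 5% percentile interval excludes zero.
#'
#' @param scores session-level scores from [session_scores()].
#' @param powers band-power table from [band_power_table()].
#' @param meta cohort metadata (for `sex`).
#' @param predictors data.frame with columns `channel` and `band`;
#'   default: all channel x band combinations present.
#' @param n_boot bootstrap iterations (>= 100; 1000 at clinical
#'   scale).
#' @param seed RNG seed.
#' @param conf confidence level of the percentile interval.
#' @return data.frame: `channel`, `band`, `coef_mean`, `coef_sd`,
#'   `ci_low`, `ci_high`, `significant`, `n_singular`.
#' @export
bootstrap_regression <- function(scores, powers, meta,
                                 predictors = NULL, n_boot = 1000,
                                 seed = 1, conf = 0.95) {
  if (n_boot < 100)
    stop("n_boot must be at least 100 for a stable percentile interval")
  if (is.null(predictors))
    predictors <- unique(powers[, c("channel", "band")])
  base <- merge(scores, meta[, c("subject_id", "sex")], by = "subject_id")
  subjects <- unique(base$subject_id)
  alpha <- 1 - conf
  out <- list()
  with_local_seed(seed, {
    # pre-draw the bootstrap panels once so every predictor sees the same
    # resampled cohorts (paired comparison across predictors)
    panels <- lapply(seq_len(n_boot), function(b)
      sample(subjects, length(subjects), replace = TRUE))
    for (pi in seq_len(nrow(predictors))) {
      ch <- predictors$channel[pi]; bd <- predictors$band[pi]
      pw <- powers[powers$channel == ch & powers$band == bd,
                   c("subject_id", "session_id", "eye_state", "power")]
      df <- merge(base, pw,
                  by = c("subject_id", "session_id", "eye_state"))
      idx_by_subj <- split(seq_len(nrow(df)), df$subject_id)
      coefs <- rep(NA_real_, n_boot)
      n_sing <- 0
      for (b in seq_len(n_boot)) {
        take <- panels[[b]]
        rows <- idx_by_subj[take]
        dfb <- df[unlist(rows, use.names = FALSE), , drop = FALSE]
        # re-label duplicated participants so the random intercept treats
        # each drawn copy as a distinct grouping unit
        dfb$subject_id <- rep(paste0(take, "#", seq_along(take)),
                              lengths(rows))
        fit <- try(fast_lmm_coef(dfb), silent = TRUE)
        if (inherits(fit, "try-error")) next
        if (fit$singular) { n_sing <- n_sing + 1; next }
        coefs[b] <- fit$coef
      }
      ok <- coefs[!is.na(coefs)]
      if (length(ok) < n_boot / 2)
        warning("predictor ", ch, "/", bd, ": more than half of the ",
                "bootstrap fits failed or were singular")
      ci <- quantile(ok, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      out[[pi]] <- data.frame(
        channel = ch, band = bd,
        coef_mean = mean(ok), coef_sd = sd(ok),
        ci_low = ci[1], ci_high = ci[2],
        significant = ci[1] > 0 | ci[2] < 0,
        n_singular = n_sing, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
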