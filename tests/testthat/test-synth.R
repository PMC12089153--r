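# Synthetic cohort generator: determinism, planted structure, artifact
# fixtures, EDF round trip.

test_that("identical spec and seed give a bit-identical cohort", {
  spec <- cohort_spec(n_subjects = 2, duration_s = 20, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$metadata, b$metadata)
  for (i in seq_along(a$recordings))
    expect_identical(a$recordings[[i]]$data, b$recordings[[i]]$data)
})

test_that("responder draw is the seeded Bernoulli draw", {
  m <- generate_metadata(cohort_spec(n_subjects = 20,
                                     responder_rate = 0.4, seed = 7))
  expect_equal(sum(m$responder), 4)   # frozen regression value
})

test_that("remission is exactly the HAM-D <= 7 criterion", {
  m <- generate_metadata(cohort_spec(n_subjects = 100, seed = 5))
  expect_identical(m$remission, m$endpoint_score <= 7)
})

test_that("zero planted effect leaves theta power class-neutral", {
  spec <- cohort_spec(n_subjects = 20, responder_rate = 0.4,
                      effect_theta = 0, effect_beta_low = 0, seed = 7,
                      duration_s = 20)
  coh <- generate_cohort(spec)
  ss <- bind_segment_sets(lapply(coh$recordings, function(r)
    segment_recording(bandpass_notch(r), NULL)))
  pw <- band_power_table(ss)
  th <- pw[pw$band == "theta" & pw$channel == "Fz", ]
  agg <- aggregate(power ~ subject_id, th, mean)
  agg$resp <- coh$metadata$responder[match(agg$subject_id,
                                           coh$metadata$subject_id)]
  expect_gt(t.test(power ~ resp, agg)$p.value, 0.05)
})

test_that("planted theta effect has the planted sign at Fz", {
  spec <- cohort_spec(n_subjects = 24, effect_theta = 2,
                      effect_beta_low = 0, duration_s = 20, seed = 9)
  coh <- generate_cohort(spec)
  meta <- coh$metadata
  pw <- vapply(coh$recordings, function(r)
    band_power_vec(r$data["Fz", ], r$rate_hz, 4, 8), numeric(1))
  subj <- vapply(coh$recordings, `[[`, "", "subject_id")
  agg <- tapply(pw, subj, mean)
  resp <- meta$responder[match(names(agg), meta$subject_id)]
  expect_lt(mean(agg[resp]), mean(agg[!resp]))
  expect_lt(t.test(agg[resp], agg[!resp])$p.value, 0.05)
})

test_that("background spectrum falls off as a power law", {
  rec <- clean_recording()
  ps <- welch_psd(rec$data["Pz", ], rec$rate_hz)
  sel <- ps$freq >= 2 & ps$freq <= 40
  slope <- coef(lm(log(ps$psd[sel]) ~ log(ps$freq[sel])))[2]
  expect_lt(slope, 0)
})

test_that("alpha power is higher eyes-closed than eyes-open", {
  coh <- generate_cohort(cohort_spec(n_subjects = 3, duration_s = 20,
                                     seed = 15))
  es <- vapply(coh$recordings, `[[`, "", "eye_state")
  subj <- vapply(coh$recordings, `[[`, "", "subject_id")
  alpha <- vapply(coh$recordings, function(r)
    band_power_vec(r$data["O1", ], r$rate_hz, 8, 13), numeric(1))
  for (s in unique(subj))
    expect_gt(alpha[subj == s & es == "EC"], alpha[subj == s & es == "EO"])
})

test_that("with all effects zero, responder is independent of covariates", {
  spec <- cohort_spec(n_subjects = 200, effect_theta = 0,
                      effect_beta_low = 0, sex_effect = 0, age_slope = 0,
                      covariates = list(extraversion = 0,
                                        reaction_time = 0),
                      seed = 20)
  m <- generate_metadata(spec)
  r <- as.numeric(m$responder)
  for (v in c("age_years", "extraversion", "reaction_time"))
    expect_lt(abs(cor(r, m[[v]])), 0.2)
  expect_lt(abs(cor(r, as.numeric(m$sex == "male"))), 0.2)
})

test_that("invalid spec fields raise configuration errors naming the field", {
  expect_error(cohort_spec(responder_rate = 1.4), "responder_rate")
  expect_error(cohort_spec(duration_s = 10), "duration_s")
  expect_error(cohort_spec(artifact_rates = list(nope = 0.1)),
               "artifact_rates")
})

test_that("artifact injection matches each rule's signature", {
  rec <- clean_recording()
  set.seed(99)
  # extreme voltage: a sample above 200 uV inside the 5-6 s window
  ev <- inject_artifact(rec, "extreme_voltage", 5)
  win <- (5 * 250 + 1):(6 * 250)
  expect_gte(max(abs(ev$data["C4", win])), 200)
  # bridging: near-identical channel pair over the whole recording
  br <- inject_artifact(rec, "bridging", 0)
  expect_lt(var(br$data["P3", ] - br$data["P4", ]), 0.5)
  # muscle: 75-95 Hz power in the injected window >= 5x recording median
  mu <- inject_artifact(rec, "muscle", 10)
  wins <- seq(0, 59)
  bp <- vapply(wins, function(w) {
    seg <- mu$data["C4", (w * 250 + 1):((w + 1) * 250)]
    band_power_vec(seg, 250, 75, 95, nperseg = 250)
  }, numeric(1))
  expect_gte(bp[wins == 10], 5 * median(bp))
  # unknown rule id errors, listing the valid ids
  expect_error(inject_artifact(rec, "wiggle", 0), "bridging")
})

test_that("EDF files round-trip recordings and metadata", {
  rec <- clean_recording()
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$eye_state, rec$eye_state)
  expect_equal(back$rate_hz, rec$rate_hz)
  expect_equal(back$channels, rec$channels)
  # 16-bit quantization bound: half of one digital step
  expect_lt(max(abs(back$data - rec$data)), 1000 / 32767)
  unlink(path)
})

test_that("write_cohort/read_cohort preserve the cohort", {
  coh <- generate_cohort(cohort_spec(n_subjects = 2, duration_s = 16,
                                     seed = 3))
  dir <- tempfile()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$recordings), 4)
  expect_equal(back$metadata$subject_id, coh$metadata$subject_id)
  expect_equal(sort(vapply(back$recordings, `[[`, "", "subject_id")),
               sort(vapply(coh$recordings, `[[`, "", "subject_id")))
  unlink(dir, recursive = TRUE)
})
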