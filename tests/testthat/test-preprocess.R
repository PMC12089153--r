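# Filtering, ocular correction, artifact detection and segmentation.

sine_recording <- function(f0, dur = 30, fs = 250) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  recording(matrix(rep(sin(2 * pi * f0 * t), 19), nrow = 19,
                   byrow = TRUE), canonical_channels(), fs)
}

fft_gain <- function(rec_in, rec_out, f0) {
  n <- ncol(rec_in$data)
  bin <- round(f0 * n / rec_in$rate_hz) + 1
  Mod(fft(rec_out$data[1, ]))[bin] / Mod(fft(rec_in$data[1, ]))[bin]
}

test_that("band-pass keeps 10 Hz, notches kill 50/60 Hz, zero maps to zero", {
  for (f0 in c(10, 50, 60)) {
    rec <- sine_recording(f0)
    g <- fft_gain(rec, bandpass_notch(rec), f0)
    if (f0 == 10) expect_true(g > 0.95 && g < 1.05)
    else expect_lte(g, 0.1)
  }
  z <- recording(matrix(0, 19, 250 * 20), canonical_channels(), 250)
  expect_equal(max(abs(bandpass_notch(z)$data)), 0)
})

test_that("filtering refuses sampling rates below the pass band", {
  rec <- recording(matrix(rnorm(19 * 150 * 20), 19), canonical_channels(),
                   150)
  expect_error(bandpass_notch(rec), "resampl")
})

test_that("regression ocular correction halves blink peaks, leaves clean data alone", {
  set.seed(5)
  recb <- inject_artifact(clean_recording(), "blink", 5)
  frecb <- bandpass_notch(recb)
  win <- (5 * 250):(11 * 250)
  before <- max(frecb$data["Fp1", win])
  after <- max(ocular_correct(frecb, "regression")$data["Fp1", win])
  expect_lte(after, 0.5 * before)
  # identity pass-through
  expect_identical(ocular_correct(frecb, "none"), frecb)
  # blink-free recording: broadband RMS changes by no more than 10%
  frec <- filtered_recording()
  corr <- ocular_correct(frec, "regression")
  expect_lt(abs(sd(corr$data) / sd(frec$data) - 1), 0.1)
})

test_that("ica method falls back to regression with a warning when unavailable", {
  short <- generate_cohort(cohort_spec(n_subjects = 1, duration_s = 20,
                                       seed = 8))$recordings[[1]]
  expect_warning(ocular_correct(bandpass_notch(short), "ica"),
                 "regression")
  expect_warning(ocular_correct(filtered_recording(), "ica"),
                 "no ICA backend")
})

test_that("a 250 uV spike is reported as extreme_voltage near its onset", {
  set.seed(99)
  rec <- inject_artifact(clean_recording(), "extreme_voltage", 5)
  rep_ <- detect_artifacts(bandpass_notch(rec))
  ev <- rep_[rep_$rule == "extreme_voltage", ]
  expect_gt(nrow(ev), 0)
  expect_true(any(ev$start_s <= 6 & ev$end_s >= 5))
})

test_that("a clean recording yields no extreme_voltage or bridging entries", {
  rep_ <- detect_artifacts(filtered_recording())
  expect_equal(sum(rep_$rule %in% c("extreme_voltage", "bridging")), 0)
})

test_that("a duplicated channel pair is reported as bridging, naming the pair", {
  set.seed(99)
  rec <- inject_artifact(clean_recording(), "bridging", 0)
  rep_ <- detect_artifacts(bandpass_notch(rec))
  br <- rep_[rep_$rule == "bridging", ]
  expect_equal(nrow(br), 1)
  expect_equal(br$channel, "P3|P4")
})

test_that("disabling one rule never changes another rule's entries", {
  set.seed(99)
  rec <- inject_artifact(inject_artifact(clean_recording(), "muscle", 10),
                         "extreme_voltage", 20)
  frec <- bandpass_notch(rec)
  full <- detect_artifacts(frec)
  no_muscle <- detect_artifacts(frec, artifact_config(
    rules = setdiff(artifact_rules(), "muscle")))
  expect_equal(no_muscle[no_muscle$rule != "muscle", ],
               full[full$rule != "muscle", ], ignore_attr = TRUE)
})

test_that("segmentation yields the window-count oracle and exact shapes", {
  frec <- filtered_recording()            # 60 s
  ss <- segment_recording(frec, NULL)
  expect_equal(n_segments(ss), floor((60 - 16) / 1) + 1)   # 45
  expect_true(all(ss$kept))
  expect_equal(dim(ss$data)[2:3], c(19, 2000))
})

test_that("a full-cover artifact rejects every segment", {
  frec <- filtered_recording()
  rep_ <- data.frame(start_s = 0, end_s = 60, rule = "bridging",
                     channel = NA, score = 1)
  ss <- segment_recording(frec, rep_)
  expect_equal(n_segments(ss), 45)
  expect_equal(sum(ss$kept), 0)
  expect_true(all(vapply(ss$reject_reason, identical, TRUE, "bridging")))
})

test_that("short recordings give an empty segment set with a warning", {
  rec <- recording(matrix(rnorm(19 * 10 * 250), 19), canonical_channels(),
                   250)
  expect_warning(ss <- segment_recording(rec, NULL), "16")
  expect_equal(n_segments(ss), 0)
})

test_that("a pure tone keeps its frequency through resampling", {
  rec <- sine_recording(10, dur = 30)
  ss <- segment_recording(rec, NULL)
  seg <- ss$data[1, 1, ]
  freqs <- (seq_along(seg) - 1) * 125 / length(seg)
  expect_equal(freqs[which.max(Mod(fft(seg))[1:1000])], 10)
})

test_that("rejection is monotone in the artifact report", {
  frec <- filtered_recording()
  r1 <- data.frame(start_s = 5, end_s = 6, rule = "muscle", channel = "C4",
                   score = 9)
  r2 <- rbind(r1, data.frame(start_s = 30, end_s = 31, rule = "kurtosis",
                             channel = "Cz", score = 9))
  k1 <- sum(segment_recording(frec, r1)$kept)
  k2 <- sum(segment_recording(frec, r2)$kept)
  expect_lte(k2, k1)
  # kept and reject_reason are mutually exclusive
  ss <- segment_recording(frec, r2)
  expect_true(all(lengths(ss$reject_reason[ss$kept]) == 0))
  expect_true(all(lengths(ss$reject_reason[!ss$kept]) > 0))
})

test_that("segment sets round-trip through the disk container", {
  frec <- filtered_recording()
  rep_ <- data.frame(start_s = 5, end_s = 6, rule = "muscle",
                     channel = "C4", score = 9)
  ss <- segment_recording(frec, rep_)
  dir <- tempfile()
  write_segments(ss, dir)
  expect_true(file.exists(file.path(dir, "index.tsv")))
  back <- read_segments(dir)
  expect_equal(back$data, ss$data)
  expect_equal(back$kept, ss$kept)
  expect_equal(back$reject_reason, ss$reject_reason)
  unlink(dir, recursive = TRUE)
})

test_that("montage mapping canonicalizes order, drops extras, reports gaps", {
  rec <- clean_recording()
  shuffled <- recording(rec$data[19:1, ], rec$channels[19:1], rec$rate_hz)
  out <- map_montage(shuffled)
  expect_equal(out$channels, canonical_channels())
  expect_equal(out$data["Fz", ], unname(rec$data["Fz", ]),
               ignore_attr = TRUE)
  # 21-channel input mapped down to 19
  extra <- recording(rbind(rec$data, rnorm(ncol(rec$data)),
                           rnorm(ncol(rec$data))),
                     c(rec$channels, "A1", "A2"), rec$rate_hz)
  tbl <- setNames(canonical_channels(), canonical_channels())
  expect_equal(nrow(map_montage(extra, tbl)$data), 19)
  # missing target name errors, naming the gap
  tbl2 <- tbl[names(tbl) != "Pz"]
  expect_error(map_montage(rec, tbl2), "Pz")
})
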