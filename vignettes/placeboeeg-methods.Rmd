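---
title: "Predicting placebo response from resting-state EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting placebo response from resting-state EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the science and the design choices behind
`placeboeeg`: what each stage of the pipeline computes, which parameters
matter and why their defaults are what they are, what the synthetic
cohort generator does and does not emulate, and where the genuinely open
design decisions were settled.

## The problem

In antidepressant trials, a third or more of placebo-arm patients remit
on their own — the placebo response. A model that predicts, from a
pre-treatment resting-state EEG, which patients are likely placebo
responders would let trials stratify or statistically control for them.
The pipeline here treats this as a binary classification problem on raw
EEG segments: each subject contributes eyes-open (EO) and eyes-closed
(EC) resting recordings; segments are classified by a small
convolutional network; segment scores are aggregated to subject scores;
and the resulting predictions are interrogated with spectral and
behavioural statistics.

## Preprocessing

Raw recordings pass through, in order:

* **Montage mapping.** Everything downstream expects the 19-channel
  10–20 montage in a fixed order (`canonical_channels()`). Recordings
  from denser nets are mapped through a user-supplied conversion table
  (`map_montage()`); the table is an input because vendor-specific
  correspondence tables are not universal.
* **Filtering.** A zero-phase 0.5–100 Hz Butterworth band-pass with
  2nd-order notch stops at 50 and 60 Hz (`bandpass_notch()`). The
  band-pass is realized as a high-pass/low-pass cascade: a direct
  band-pass design at a normalized corner of 0.5 Hz / 125 Hz is
  numerically fragile, while the cascade is well-conditioned and has
  the same order. Filtering happens at the native rate, before any
  resampling, so the 75–95 Hz muscle band is still observable.
* **Ocular correction** (`ocular_correct()`). The default method builds
  a virtual electro-oculogram — the 4 Hz low-passed average of Fp1 and
  Fp2 — detects blink peaks above 4 robust SDs, masks the regressor to
  the detected blink neighbourhoods, and subtracts each channel's
  least-squares projection onto it. Masking matters: without it the
  regression would also remove genuine slow frontal activity from
  blink-free data. On blink-free recordings the operation is close to
  the identity (the regressor is zero almost everywhere). ICA-based
  correction is supported as a pluggable backend (`ica_fun`); with no
  backend, or with recordings under 60 s where a decomposition is
  unreliable, the method falls back to the regression with a warning.
* **Artifact detection** (`detect_artifacts()`). Six independent rules,
  each with its own statistic and time base, reported in seconds so the
  rejection logic is sampling-rate independent:
  1. *muscle* — log 75–95 Hz power per 1-s window, robust z > 5;
  2. *extreme voltage* — any |sample| > 200 µV;
  3. *abrupt transition* — the difference of adjacent 0.5-s window
     means, thresholded at 4 recording SDs;
  4. *kurtosis* — per-window sample kurtosis, z > 4 pooled over
     channels and windows **and** an absolute floor of 7;
  5. *blink* — three or more frontal transients above 4 robust SDs of
     the virtual EOG within 16 s ("persistent blinks");
  6. *bridging* — variance of a channel-pair difference below 0.5 µV²
     over the whole recording (electrical distance).

  Two numerical choices deserve explanation. First, the per-window
  rules use robust (median/MAD) centring where the statistic is
  roughly symmetric: with ~100 windows × 19 channels per recording, a
  plain mean/SD z at conventional thresholds would flag several clean
  windows per recording by chance alone. Second, the kurtosis rule
  keeps a plain-SD z *plus* an absolute floor: the kurtosis estimator
  is strongly right-skewed on oscillatory signals (amplitude-modulated
  narrowband activity produces scale mixtures), so a z-score alone
  cannot distinguish the clean tail from genuine spikes; Gaussian data
  sit at kurtosis 3, and the floor of 7 is far outside the clean tail
  while sparse spike trains reach 10 and beyond. Similarly, a literal
  "2 SDs above baseline" rule for abrupt transitions fires on ~2–5% of
  all Gaussian samples by construction; the implemented baseline-jump
  statistic (difference of adjacent half-second means) is near zero
  for oscillations and bursts but large for true level shifts, and the
  4-SD default separates the two cleanly. All thresholds live in
  `artifact_config()`.
* **Segmentation** (`segment_recording()`). The recording is resampled
  to 125 Hz (polyphase FIR) and cut into half-open 16-s windows
  starting at every integer second — i.e. 15 s overlap — giving
  `floor(duration - 16) + 1` segments of exactly `[19 × 2000]`. Any
  window that intersects a flagged artifact interval is excluded, with
  its rule ids recorded. An equivalent 8-s/250 Hz convention would
  produce the same tensor shape; the 16-s/125 Hz convention is the
  package default and the alternative is reachable through the
  `target_rate`/`win_s` arguments.

## Augmentation

Five stochastic operators expand the training set
(`augment_segment()`): re-referencing to a random channel, additive
Gaussian noise with SD drawn uniformly from [0, 0.2] *in units of each
channel's own SD* (the unit makes the perturbation scale-free across
recording systems), amplification of one random channel by a factor up
to 1.2, time reversal, and horizontal compression by a factor in
[0.5, 1] with zero padding back to 2000 samples (Fourier-domain
resampling). Each operator is applied independently with probability
0.5. Augmentation only ever touches training batches; validation and
test segments pass through untouched. All draws come from R's RNG, so
a seeded augmentation stream is bit-reproducible.

## The classifier

`model_spec()` / `build_model()` define an eight-block 1-D CNN: each
block is convolution → batch normalization → ReLU, with the 19
electrodes as input channels of the first convolution and time as the
only spatial axis (the standard arrangement for raw-EEG networks). A
pooling stage collapses time — global average pooling by default, with
adaptive max pooling available as a configuration switch — and a linear
head maps the pooled features to one logit per segment;
`predict_proba()` is its sigmoid.

The architecture family is fixed in its block count (eight), the
per-block structure, the pooling-plus-linear head and the logit
output; widths, kernels and strides are free parameters. The defaults here —
widths 8→8→16→16→32→32→64→64, kernel 7, stride 2 at every even block —
are sized for single-CPU training: one epoch over 5000 segments runs
in under a minute (a guarded performance test enforces this), and all
of these are plain `model_spec` arguments. The smoke profile uses a
51-sample first kernel with stride 2 at L1: at 125 Hz a 7-sample kernel
spans only 56 ms, too short to form band-selective filters in one
layer, while 51 samples (~0.4 s) cover a full theta cycle — the
standard long-first-kernel design of raw-EEG CNNs.

The network, its analytic gradients (including batch-norm backward),
BCE-with-logits loss, AdamW, the plateau scheduler and early stopping
are implemented in RcppArmadillo + R inside the package. Numerical
notes: batch-norm uses ε = 1e-5 and momentum 0.1 running statistics;
internal arithmetic is single precision (the conventional precision
for this model class; gradients are verified against central finite
differences in the tests); weight decay is decoupled and applied to
convolution and head weights only, never to biases or batch-norm
scale/shift.

## Two-stage training and cross-validation

`make_folds()` assigns whole subjects to five folds (sizes within one,
optional label stratification); iteration *i* tests on fold *i*,
validates on fold *i*+1 (mod 5) and trains on the rest, so every
subject is tested exactly once per rotation and EO/EC sessions can
never straddle roles. A hard assertion in `fold_rotation()` re-checks
the partition on every call.

Stage one (`train_two_stage()`) trains the full network to predict
remission — endpoint HAM-D-17 ≤ 7 — on all training-fold subjects of
both arms. Stage two restarts from that checkpoint, restricts training
to placebo-arm subjects, and updates only block L8 and the head; blocks
L1–L7 are frozen *including their batch-norm buffers* (frozen blocks
run in evaluation mode during fine-tuning), which is what makes the
bitwise freeze contract testable. The placebo "responder" label is the
same remission criterion restricted to the placebo arm: remission is
defined once and reused rather than inventing a second endpoint. Early stopping watches the
validation loss (the conventional monitored quantity);
the plateau scheduler halves the learning rate after 10 stagnant
epochs by default.

`train_ensemble()` trains *n* models (20 at clinical scale), each
with its own seed and its own fold split, and stacks their prediction
tables. Each ensemble member trains its own baseline before
fine-tuning; per-member baselines keep the members exchangeable.

## Evaluation

`aggregate_subject_scores()` averages hierarchically — models within a
segment, segments within a session, sessions within a subject — so a
subject with unequal numbers of kept EO/EC segments is not dominated by
the longer session. `bootstrap_metrics()` resamples the *model* axis
per segment with replacement, re-aggregates, thresholds at 0.5
probability (the neutral operating point on a probability scale, and a
parameter), computes loss/AUC/balanced
accuracy/sensitivity/specificity over subjects, and reports each as
mean ± SD over repetitions. A subject-level bootstrap is available
behind the `unit` flag as a robustness variant. AUC uses the tie-aware
rank (Mann–Whitney) form; the tests pin it to an O(n²) pairwise
concordance oracle.

## Spectral regression

`band_power_table()` computes absolute power in theta (4–8), alpha
(8–13), lower beta (13–20) and upper beta (20–30 Hz) per channel via
Welch PSD — 4-s Hann windows at 50% overlap (window length is a free
parameter of Welch's method; 4 s gives 0.25 Hz resolution, ample for
these band edges) — integrated over each band, averaged over a
session's kept segments.

`bootstrap_regression()` fits, for each (channel, band) predictor,

```
score ~ power_z + sex * eye_state + (1 | subject)
```

with the session-level prediction score as response (session-level is
the finest level at which eye state is a meaningful
regressor, and the subject random intercept absorbs the within-subject
correlation). Predictor power is z-scored within each fitting sample so
coefficients are comparable across channels and bands. Participants are
resampled with replacement over 1000 iterations (200 at smoke scale);
drawn duplicates are re-labelled as distinct grouping units so the
random effect treats each draw as a new participant. Significance is
the two-tailed 5% percentile rule: an effect is significant when the
2.5–97.5% interval of the bootstrap coefficient distribution excludes
zero. Singular fits are flagged, counted and excluded from the tally.
The bootstrap loop goes through lme4's modular interface for speed; its
equality with the plain `lmer` fit is asserted in the tests.

## Covariate screening

`correlate_covariates()` computes Pearson correlations between
subject-level prediction scores and each covariate of a user-supplied
family, with pairwise-complete handling of missing values, two-sided
p-values and Holm's step-down correction applied within the family. The
family is an input rather than a hard-coded list because covariate
panels differ between datasets. Degenerate covariates (zero variance,
fewer than three complete pairs) are reported as skipped rather than
silently dropped.

## The synthetic cohort generator

Clinical EEG datasets with placebo outcomes are access-restricted, so
the package is exercised end to end on synthetic cohorts
(`cohort_spec()` / `generate_cohort()`). The signal model is
deliberately minimal: per channel, 1/f Gaussian background (log–log
slope ≈ −1 over 2–40 Hz) with per-subject RMS drawn from 8–14 µV,
plus four band-limited Gaussian oscillators (theta/alpha/lower
beta/upper beta, mean RMS 4/6/3/2 µV) whose per-subject, per-channel
amplitudes are log-normal with sigma = 0.25, plus 2 uV sensor noise —
total RMS in the 10–30 µV range so that the 200 µV voltage rule can
only fire on injected events. Eyes-closed sessions carry 1.8× alpha,
mirroring the classic EO/EC alpha reactivity.

Class structure is planted exactly where the downstream analyses look
for it: responders' theta amplitude at Fz/Cz/F8/C3 and lower-beta
amplitude at F3/F4 are shifted down by `effect_theta` /
`effect_beta_low` standardized (log-amplitude) units; responder status
itself follows a logistic model with a male log-odds shift
(`sex_effect`, default −0.5) and an age slope (`age_slope`, default
−0.5 per SD of age, ages uniform 18–65); behavioural covariates are
Gaussians with configurable correlations to responder status. Clinical findings of this kind relate band power to the *model's
predictions*, not to ground-truth responder status, so the planted
effect sizes are free parameters of the simulation, not claims about
any clinical dataset. `inject_artifact()` adds one event of any
of the six artifact classes, each shaped to trip exactly its own rule
(e.g. burst-type events carry flat-top envelopes so they do not leak
into the kurtosis statistic).

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: ERP morphology, volume
conduction and inter-channel correlation structure, non-stationarity
beyond oscillator envelopes, site and hardware effects, and any true
coupling between EEG and clinical outcome. Recovery results on this
generator demonstrate that the pipeline's machinery is correct and
able to find planted structure of realistic magnitude; they say
nothing about clinical effect sizes.

## Problem sizes, profiles and determinism

The `full_scale` profile carries the clinical-scale conditions: 2-minute
EO/EC recordings, AdamW at 3e-5 (baseline) / 1e-4 (fine-tune) with
weight decay 0.1, batches of 512 segments, patience-10 plateau
scheduling, 20-epoch early stopping, a 20-model ensemble and
1000-repetition bootstraps.

The `smoke` profile is the package's desk-scale configuration, used by
the test-suite and the acceptance script: 60 subjects, 24-s recordings
(nine 16-s windows per session), strong planted effects
(`effect_theta = effect_beta_low = 3`, at which the subject-level
band-power oracle is near-separable), the long-first-kernel network
described above, learning rates 1.5e-3/3e-3 with batches of 64 and at
most 12 epochs, a single ensemble member, and 200-repetition
bootstraps. Two profile choices depart from the full-scale values and are
deliberate problem-size scalings rather than method changes: the
learning rates (the full-scale rates suit ~30k-segment training
runs and move the weights by about 1% of their initialization over a
~600-segment smoke run — underfitting by construction) and
augmentation, which is disabled at smoke scale (with ~40 training
subjects the invariances the operators demand dominate the sample;
the operators themselves are exhaustively unit-tested and on by
default in `train_config()`).

Determinism: every stochastic component takes a seed, and seeded runs
are bit-reproducible; `run_pipeline()` fans one global seed out to
per-stage seeds by fixed offsets, caches stage artifacts in the run
directory, resumes from whatever exists, and stamps every result file
with the configuration hash and seed.

## Known limitations

* The fine-tuning stage inherits whatever biases the remission
  pre-training learned from both arms; the package does not attempt
  causal separation of placebo response from treatment response.
* The bridging and blink rules are whole-recording and frontal-only
  respectively; localized bridging between non-adjacent channels or
  lateral eye movements are out of scope.
* The mixed-model bootstrap treats drawn participants as independent
  clones; alternatives (weighted likelihoods, cluster bootstrap-t)
  are not implemented.
* Band powers are absolute; a relative-power variant is deliberately
  out of scope.
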