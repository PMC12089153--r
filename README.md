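# placeboeeg

Predicting placebo response in depression trials from resting-state EEG.

Placebo response rates of 30–40% are one of the main obstacles in
antidepressant trials: they mask true drug effects and inflate required
sample sizes. If placebo responders could be identified from a cheap,
widely available measurement such as resting-state EEG, trials could
stratify or covary them out. `placeboeeg` implements an end-to-end
pipeline for this problem:

1. **Preprocessing** — 0.5–100 Hz band-pass with 50/60 Hz notches
   (zero-phase), regression-based ocular correction (ICA pluggable), six
   independent artifact-rejection rules (muscle 75–95 Hz power, voltage
   > 200 µV, abrupt baseline transitions, high kurtosis, persistent
   blinks, electrode bridging), then segmentation into 16-s windows with
   15-s overlap at 125 Hz. Every kept segment is a `[19 × 2000]` array
   on the canonical 10–20 montage
   (Fp1/2, F7/8, F3/4, Fz, T7/8, C3/4, Cz, P7/8, P3/4, Pz, O1/2).
2. **Augmentation** — random-channel re-referencing, Gaussian noise
   (SD ~ U[0, 0.2] of channel SD), single-channel amplification up to
   1.2×, time reversal, and horizontal compression with zero padding;
   training segments only.
3. **Classifier** — an eight-block 1-D CNN (conv → batch norm → ReLU),
   global average pooling (adaptive max available) and a linear head
   producing one placebo-response logit per segment. Implemented from
   scratch on RcppArmadillo (forward, analytic gradients, AdamW,
   reduce-on-plateau scheduling, early stopping).
4. **Two-stage training** — a baseline model first learns to predict
   remission (HAM-D-17 ≤ 7) on all subjects; it is then fine-tuned on
   placebo-arm subjects only, updating just block L8 and the head while
   all other weights stay frozen. Training uses subject-grouped 5-fold
   cross-validation (3/5 train, 1/5 validation, 1/5 test) so that no
   subject's segments leak across roles.
5. **Evaluation** — predictions of an ensemble of independently split
   models are averaged hierarchically (models → segments → sessions →
   subjects) and the metric suite (BCE loss, AUC, balanced accuracy,
   sensitivity, specificity) is reported as mean ± SD over a bootstrap
   that resamples the model axis per segment.
6. **Statistical follow-up** — absolute band power (theta 4–8, alpha
   8–13, lower beta 13–20, upper beta 20–30 Hz; Welch, 4-s Hann windows)
   feeds a bootstrapped mixed-effects regression
   `score ~ power_z + sex * eye_state + (1 | subject)` with participants
   resampled with replacement; and subject-level scores are screened
   against behavioural covariates with Holm-corrected Pearson
   correlations.

Because the clinical datasets this kind of model is built on are
access-restricted, the package ships a **synthetic cohort generator**:
19-channel recordings made of 1/f background plus band-limited
oscillators, with plantable class effects (lower theta at Fz/Cz/F8/C3
and lower beta at F3/F4 in responders), a sex effect and an age slope on
responder log-odds, injectable artifacts matching each rejection rule,
and EDF/CSV output. Every stage of the pipeline is exercised and tested
against this generator.

## Worked example

```r
library(placeboeeg)

# a small cohort with strong planted spectral effects
spec <- cohort_spec(n_subjects = 12, duration_s = 20,
                    effect_theta = 2, seed = 9)
coh  <- generate_cohort(spec)
segs <- preprocess_cohort(coh$recordings)
segs
#> <segment_set> 120 segments [19 x 2000], 112 kept (93%)

# theta power at Fz separates the planted classes
pw  <- band_power_table(segs)
th  <- subset(pw, band == "theta" & channel == "Fz")
agg <- aggregate(power ~ subject_id, th, mean)
agg$responder <- coh$metadata$responder[
  match(agg$subject_id, coh$metadata$subject_id)]
tapply(agg$power, agg$responder, mean)
#>    FALSE     TRUE
#> 26.40265 19.13088

auc_rank(-agg$power, agg$responder)
#> [1] 0.8571429
```

Responders were planted with a 2-SD lower theta amplitude at four
channels; the band-power table recovers that as clearly reduced
absolute theta power at Fz and a subject-level AUC of 0.86 for the
(negated) power ranking — at n = 12 with a 2-SD planted shift, a
reasonable separation for a single channel and band.

The full pipeline — synthesis, preprocessing, two-stage training,
bootstrap metrics, spectral regression and covariate screening — runs
from one configuration object:

```r
cfg <- pipeline_config("smoke", seed = 1)
res <- run_pipeline(cfg, "run")       # ~10 min on one CPU
res$results$metrics$auc
```

A thin command-line wrapper is installed under `inst/cli/placebo-eeg`:

```sh
Rscript inst/cli/placebo-eeg synth --out cohort/ --seed 1
Rscript inst/cli/placebo-eeg run --out run/ --profile smoke --seed 1
```

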