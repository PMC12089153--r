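# Shared fixtures, memoized across test files (testthat loads helpers
# once per run; heavy cohorts and training runs are built on first use).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# one clean 60-s recording (no injected artifacts)
clean_recording <- function() fixture("clean_rec", function() {
  generate_cohort(cohort_spec(n_subjects = 1, duration_s = 60,
                              seed = 11))$recordings[[1]]
})

filtered_recording <- function() fixture("filt_rec", function() {
  bandpass_notch(clean_recording())
})

# a tiny architecture for fast model/optimizer tests
tiny_spec <- function(init_seed = 2) {
  model_spec(channels = c(2, 2, 3, 3, 4, 4, 5, 5), kernel = 3,
             in_channels = 4, in_len = 40, init_seed = init_seed)
}

tiny_batch <- function(n = 6, seed = 3) {
  set.seed(seed)
  list(X = array(rnorm(n * 4 * 40), c(n, 4, 40)),
       y = rep_len(c(1, 0), n))
}

# ---- smoke-scale cohort and training runs (shared by the acceptance and
# train tests; ~1 min to build the segments, ~8 min per training run) ----

smoke_cohort <- function() fixture("smoke_cohort", function() {
  spec <- cohort_spec(n_subjects = 60, duration_s = 24, effect_theta = 3,
                      effect_beta_low = 3, seed = 101)
  coh <- generate_cohort(spec)
  list(segments = preprocess_cohort(coh$recordings),
       meta = coh$metadata)
})

smoke_model_spec <- function(init_seed = 11) {
  model_spec(kernel = c(51, rep(7, 7)), strides = rep(c(2, 1), 4),
             init_seed = init_seed)
}

smoke_cfg <- function(stage, seed) {
  train_config(stage,
               lr = if (stage == "baseline") 1.5e-3 else 3e-3,
               batch_size = 64, max_epochs = 12, early_stop_epochs = 12,
               plateau_patience = 5, augment = NULL, seed = seed)
}

# pooled fine-tuned placebo-arm subject scores for a (possibly
# label-permuted) smoke cohort
smoke_run <- function(meta, segments, stage = "finetune") {
  folds <- make_folds(meta$subject_id, 5, seed = 31,
                      labels = meta$responder)
  run <- train_two_stage(segments, meta, folds, smoke_model_spec(),
                         smoke_cfg("baseline", 21),
                         smoke_cfg("finetune", 22))
  plac <- meta$subject_id[meta$arm == "placebo"]
  p <- run$predictions[run$predictions$stage == stage &
                         run$predictions$subject_id %in% plac, ]
  scores <- aggregate_subject_scores(p)
  y <- setNames(as.numeric(meta$responder), meta$subject_id)
  list(scores = scores, labels = y[names(scores)], run = run)
}

smoke_recovery <- function() fixture("smoke_recovery", function() {
  sc <- smoke_cohort()
  smoke_run(sc$meta, sc$segments)
})

smoke_permuted <- function() fixture("smoke_permuted", function() {
  sc <- smoke_cohort()
  meta <- sc$meta
  set.seed(33)
  perm <- sample(nrow(meta))
  meta$responder <- meta$responder[perm]
  meta$remission <- meta$remission[perm]
  smoke_run(meta, sc$segments)
})
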