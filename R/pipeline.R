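# End-to-end pipeline: synth -> preprocess -> train -> evaluate ->
# spectra -> correlate, with cached, resumable stage artifacts in a run
# directory. The global seed fans out to per-stage seeds by fixed
# offsets; every numeric result file carries the configuration hash and
# seed.

SEED_OFFSETS <- c(synth = 0L, train = 1000L, evaluate = 2000L,
                  spectra = 3000L)

#' Pipeline configuration
#'
#' Two profiles are provided. `"smoke"` is a desk-scale configuration
#' (small cohort, short recordings, strong planted effects, a narrow
#' network and short training runs) that exercises every stage end to end
#' on one CPU in minutes. `"full_scale"` carries the clinical-scale study
#' conditions: 2-minute EO/EC recordings, AdamW at 3e-5/1e-4 with weight
#' decay 0.1 and batches of 512, a 20-model ensemble and 1000 bootstrap
#' repetitions.
#'
#' @param profile `"smoke"` or `"full_scale"`.
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#' @param overrides named list of profile entries to replace wholesale
#'   (top-level keys: `cohort`, `model`, `train_baseline`,
#'   `train_finetune`, `n_models`, `n_boot`, `spectra_predictors`,
#'   `correlate_family`). Replacement is shallow: an override block
#'   stands in for the profile's block, with the constructor defaults
#'   filling whatever it omits.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = c("smoke", "full_scale"), seed = 1,
                            overrides = list()) {
  profile <- match.arg(profile)
  base <- if (profile == "smoke") {
    list(
      cohort = list(n_subjects = 60, duration_s = 24, effect_theta = 3,
                    effect_beta_low = 3),
      model = list(kernel = c(51, rep(7, 7)), strides = rep(c(2, 1), 4),
                   init_seed = 1L),
      train_baseline = list(lr = 1.5e-3, batch_size = 64, max_epochs = 12,
                            early_stop_epochs = 12, plateau_patience = 5,
                            augment = NULL),
      train_finetune = list(lr = 3e-3, batch_size = 64, max_epochs = 12,
                            early_stop_epochs = 12, plateau_patience = 5,
                            augment = NULL),
      n_models = 1, n_boot = 200,
      spectra_predictors = data.frame(
        channel = c("Fz", "Cz", "F8", "C3", "F3", "F4"),
        band = c(rep("theta", 4), rep("beta_low", 2)),
        stringsAsFactors = FALSE),
      correlate_family = c("age_years", "extraversion", "reaction_time"))
  } else {
    list(
      cohort = list(n_subjects = 141, duration_s = 120),
      model = list(init_seed = 1L),
      train_baseline = list(),     # clinical-scale defaults: lr 3e-5, batch 512
      train_finetune = list(),     # lr 1e-4, frozen L1-L7
      n_models = 20, n_boot = 1000,
      spectra_predictors = NULL,   # all channel x band combinations
      correlate_family = c("age_years", "extraversion", "reaction_time"))
  }
  cfg <- base
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg$profile <- profile
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  rlang::hash(unclass(cfg))
}

stamp_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  writeLines(sprintf("# placeboeeg run  config_hash=%s  seed=%d",
                     config_hash(cfg), cfg$seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  close(con)
  invisible(path)
}

read_stamped_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes synth, preprocess, train, evaluate, spectra and correlate in
#' order, writing stage artifacts into `out_dir`. Stages whose outputs
#' already exist are skipped, so a partially completed run resumes where
#' it stopped (delete an artifact to recompute it and everything after
#' it that reads it). Deterministic for a given configuration and seed.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return Named list of result-file paths, invisibly; key results are
#'   also returned under `results`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = "run") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(config_hash = config_hash(cfg),
                            seed = cfg$seed, profile = cfg$profile),
                       file.path(out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE)
  paths <- list(
    cohort = file.path(out_dir, "cohort"),
    segments = file.path(out_dir, "segments.rds"),
    preds = file.path(out_dir, "predictions.tsv"),
    metrics = file.path(out_dir, "metrics.json"),
    spectra = file.path(out_dir, "spectra.tsv"),
    correlations = file.path(out_dir, "correlations.tsv"))

  # -- synth ---------------------------------------------------------------
  meta_csv <- file.path(paths$cohort, "metadata.csv")
  if (!file.exists(meta_csv)) {
    spec <- do.call(cohort_spec,
                    c(cfg$cohort,
                      list(seed = cfg$seed + SEED_OFFSETS[["synth"]])))
    write_cohort(generate_cohort(spec), paths$cohort)
  }
  cohort <- read_cohort(paths$cohort)
  meta <- cohort$metadata
  meta$responder <- as.logical(meta$responder)
  meta$remission <- as.logical(meta$remission)

  # -- preprocess ----------------------------------------------------------
  if (!file.exists(paths$segments)) {
    segs <- preprocess_cohort(cohort$recordings)
    saveRDS(segs, paths$segments)
  }
  segs <- readRDS(paths$segments)

  # -- train ---------------------------------------------------------------
  if (!file.exists(paths$preds)) {
    mspec <- do.call(model_spec, cfg$model)
    cb <- do.call(train_config, c(list(stage = "baseline"),
                                  cfg$train_baseline))
    cf <- do.call(train_config, c(list(stage = "finetune"),
                                  cfg$train_finetune))
    ens <- train_ensemble(segs, meta, n_models = cfg$n_models,
                          base_seed = cfg$seed + SEED_OFFSETS[["train"]],
                          spec = mspec, cfg_base = cb, cfg_ft = cf)
    stamp_tsv(ens$predictions, paths$preds, cfg)
  }
  preds <- read_stamped_tsv(paths$preds)

  # -- evaluate ------------------------------------------------------------
  plac <- meta$subject_id[meta$arm == "placebo"]
  y <- setNames(as.numeric(meta$responder), meta$subject_id)
  pf <- preds[preds$stage == "finetune" & preds$subject_id %in% plac, ]
  if (!file.exists(paths$metrics)) {
    rep_ <- bootstrap_metrics(pf, y, n_boot = cfg$n_boot,
                              seed = cfg$seed + SEED_OFFSETS[["evaluate"]])
    jsonlite::write_json(
      c(list(config_hash = config_hash(cfg), seed = cfg$seed),
        lapply(rep_[c("loss", "auc", "bacc", "sensitivity",
                      "specificity")], as.list),
        list(n_boot = rep_$n_boot)),
      paths$metrics, auto_unbox = TRUE, digits = NA)
  }

  # -- spectra -------------------------------------------------------------
  if (!file.exists(paths$spectra)) {
    powers <- band_power_table(segs)
    sscores <- session_scores(pf)
    reg <- bootstrap_regression(sscores, powers, meta,
                                predictors = cfg$spectra_predictors,
                                n_boot = cfg$n_boot,
                                seed = cfg$seed + SEED_OFFSETS[["spectra"]])
    stamp_tsv(reg, paths$spectra, cfg)
  }

  # -- correlate -----------------------------------------------------------
  if (!file.exists(paths$correlations)) {
    sc <- aggregate_subject_scores(pf)
    cors <- correlate_covariates(sc, meta[meta$subject_id %in% plac, ],
                                 cfg$correlate_family)
    stamp_tsv(cors, paths$correlations, cfg)
  }

  out <- paths
  out$results <- list(
    metrics = jsonlite::read_json(paths$metrics),
    spectra = read_stamped_tsv(paths$spectra),
    correlations = read_stamped_tsv(paths$correlations))
  invisible(out)
}
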