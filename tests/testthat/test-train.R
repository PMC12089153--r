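# Folds, leakage guards, optimizer schedule, two-stage training.

test_that("folds partition subjects with near-equal sizes", {
  f10 <- make_folds(sprintf("s%02d", 1:10), k = 5, seed = 1)
  expect_true(all(table(f10$assignment) == 2))
  f11 <- make_folds(sprintf("s%02d", 1:11), k = 5, seed = 1)
  expect_equal(sort(as.vector(table(f11$assignment)), decreasing = TRUE),
               c(3, 2, 2, 2, 2))
  expect_identical(make_folds(sprintf("s%02d", 1:11), 5, seed = 4)$assignment,
                   make_folds(sprintf("s%02d", 1:11), 5, seed = 4)$assignment)
  expect_error(make_folds(c("a", "b"), k = 5), "folds")
})

test_that("no subject ever lands in two folds and sessions co-locate", {
  subjects <- sprintf("s%02d", 1:37)
  for (seed in 1:100) {
    f <- make_folds(subjects, 5, seed = seed)
    expect_equal(sort(names(f$assignment)), subjects)   # each exactly once
    for (i in 0:4) {
      rot <- fold_rotation(f, i)
      expect_length(intersect(rot$train, rot$test), 0)
      expect_length(intersect(rot$train, rot$val), 0)
      expect_length(intersect(rot$val, rot$test), 0)
      expect_setequal(c(rot$train, rot$val, rot$test), subjects)
    }
  }
  # EO/EC segments of one subject inherit one fold through subject ids
  sc <- generate_cohort(cohort_spec(n_subjects = 5, duration_s = 16,
                                    seed = 2))
  ss <- bind_segment_sets(lapply(sc$recordings, function(r)
    segment_recording(bandpass_notch(r), NULL)))
  f <- make_folds(unique(ss$index$subject_id), 5, seed = 3)
  seg_fold <- f$assignment[ss$index$subject_id]
  expect_true(all(tapply(seg_fold, ss$index$subject_id,
                         function(v) length(unique(v))) == 1))
})

test_that("training stops after the early-stopping window and halves the rate on plateaus", {
  m <- build_model(tiny_spec())
  b <- tiny_batch(n = 16)
  cfg <- train_config("baseline", lr = 0, batch_size = 8, max_epochs = 30,
                      early_stop_epochs = 3, plateau_patience = 2,
                      augment = NULL, seed = 2)
  fit <- fit_model(m, b$X, b$y, 1:10, 11:16, cfg)
  expect_lte(nrow(fit$history), fit$best_epoch + 3)
  # plateau scheduling: with patience 2 the recorded rate halves
  cfg2 <- train_config("baseline", lr = 1e-9, batch_size = 8,
                       max_epochs = 6, early_stop_epochs = 6,
                       plateau_patience = 2, augment = NULL, seed = 2)
  fit2 <- fit_model(m, b$X, b$y, 1:10, 11:16, cfg2)
  expect_equal(fit2$history$lr[4], 0.5 * fit2$history$lr[1])
})

test_that("degenerate single-class training labels are refused", {
  m <- build_model(tiny_spec())
  b <- tiny_batch(n = 8)
  cfg <- train_config("baseline", augment = NULL)
  expect_error(fit_model(m, b$X, rep(1, 8), 1:6, 7:8, cfg),
               "single-class")
})

test_that("zero training epochs return the input checkpoint unchanged", {
  m <- build_model(tiny_spec())
  b <- tiny_batch(n = 8)
  cfg <- train_config("finetune", max_epochs = 0, augment = NULL)
  fit <- fit_model(m, b$X, b$y, 1:6, 7:8, cfg, n_frozen = 7)
  expect_identical(fit$model, m)
})

test_that("training separates a separable cohort above chance", {
  set.seed(12)
  n <- 160
  X <- array(rnorm(n * 19 * 2000), c(n, 19, 2000))
  y <- rbinom(n, 1, 0.5)
  X[y == 1, 7, ] <- X[y == 1, 7, ] * 1.5
  m <- build_model(model_spec(channels = c(4, 4, 8, 8, 8, 8, 16, 16),
                              init_seed = 5))
  cfg <- train_config("baseline", lr = 1e-3, batch_size = 32,
                      max_epochs = 4, early_stop_epochs = 4,
                      augment = NULL, seed = 9)
  fit <- fit_model(m, X, y, 1:120, 121:160, cfg)
  z <- forward_model(fit$model, X[121:160, , ])
  expect_gt(auc_rank(z, y[121:160]), 0.5)
})

test_that("the ensemble trains distinct splits covering every segment once", {
  sc <- generate_cohort(cohort_spec(n_subjects = 16, responder_rate = 0.5,
                                    duration_s = 16, seed = 13))
  segs <- bind_segment_sets(lapply(sc$recordings, function(r)
    segment_recording(bandpass_notch(r), NULL)))
  spec <- model_spec(channels = c(2, 2, 2, 2, 4, 4, 4, 4), init_seed = 1)
  cfg <- train_config("baseline", lr = 1e-3, batch_size = 16,
                      max_epochs = 1, early_stop_epochs = 1,
                      augment = NULL)
  ens <- train_ensemble(segs, sc$metadata, n_models = 2, base_seed = 13,
                        spec = spec, cfg_base = cfg,
                        cfg_ft = train_config("finetune", max_epochs = 1,
                                              augment = NULL))
  expect_false(identical(ens$folds[[1]]$assignment[
    sort(names(ens$folds[[1]]$assignment))],
    ens$folds[[2]]$assignment[sort(names(ens$folds[[2]]$assignment))]))
  for (mid in unique(ens$predictions$model_id)) {
    pf <- ens$predictions[ens$predictions$model_id == mid &
                            ens$predictions$stage == "finetune", ]
    # every kept segment is tested exactly once across the rotation
    expect_equal(sort(pf$segment_idx), which(segs$kept))
  }
})

test_that("remission pre-training does not hurt placebo fine-tuning", {
  rec <- smoke_recovery()
  sc <- smoke_cohort()
  folds <- make_folds(sc$meta$subject_id, 5, seed = 31,
                      labels = sc$meta$responder)
  # single-stage comparison on two rotations of the same cohort
  single <- train_single_stage(sc$segments, sc$meta,
                               structure(list(assignment =
                                                folds$assignment,
                                              k = 2L),
                                         class = "fold_split"),
                               smoke_model_spec(),
                               smoke_cfg("baseline", 21))
  sc_single <- aggregate_subject_scores(single)
  common <- intersect(names(sc_single), names(rec$scores))
  y <- rec$labels[common]
  expect_gte(auc_rank(rec$scores[common], y),
             auc_rank(sc_single[common], y))
})
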