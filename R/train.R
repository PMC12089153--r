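# Two-stage training under subject-grouped 5-fold cross-validation.
#
# Stage 1 ("baseline") trains the full network on all subjects to predict
# remission; stage 2 ("finetune") restarts from the stage-1 checkpoint,
# restricts training to placebo-arm subjects, and updates only block L8
# and the classifier head, with all other weights (and their batch-norm
# buffers) frozen. Optimization is AdamW with decoupled weight decay, a
# reduce-on-plateau learning-rate schedule, and early stopping on the
# validation loss.

#' Subject-grouped cross-validation folds
#'
#' Every subject (and therefore all of their EO/EC sessions and segments)
#' is assigned to exactly one of `k` folds; fold sizes differ by at most
#' one. With `labels`, subjects are approximately stratified by label.
#'
#' @param subjects character vector of subject ids (one entry per
#'   subject).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @param labels optional per-subject labels for stratification, aligned
#'   with `subjects`.
#' @return A `fold_split`: list with `assignment` (named fold index,
#'   0-based) and `k`.
#' @export
make_folds <- function(subjects, k = 5, seed = 1, labels = NULL) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("subject ids must be unique")
  n <- length(subjects)
  if (n < k) stop(n, " subjects cannot fill ", k, " folds")
  with_local_seed(seed, {
    if (is.null(labels)) {
      ord <- sample(subjects)
    } else {
      # shuffle within label strata, then concatenate: cyclic dealing
      # below keeps overall fold sizes within one of each other while
      # approximately balancing labels across folds
      ord <- unlist(lapply(split(subjects, labels), sample), use.names = FALSE)
    }
    assignment <- setNames((seq_len(n) - 1L) %% k, ord)
  })
  structure(list(assignment = assignment, k = as.integer(k)),
            class = "fold_split")
}

#' Train/validation/test roles for one cross-validation iteration
#'
#' Iteration `i` tests on fold `i`, validates on fold `(i + 1) mod k` and
#' trains on the remaining folds.
#'
#' @param folds a [make_folds()] result.
#' @param i iteration index, 0-based.
#' @return list of subject-id character vectors `train`, `val`, `test`.
#' @export
fold_rotation <- function(folds, i) {
  k <- folds$k
  test_f <- i %% k
  val_f <- (i + 1) %% k
  a <- folds$assignment
  out <- list(train = names(a)[!a %in% c(test_f, val_f)],
              val = names(a)[a == val_f],
              test = names(a)[a == test_f])
  # leakage guard: roles must partition the subjects
  stopifnot(length(intersect(out$train, out$val)) == 0,
            length(intersect(out$train, out$test)) == 0,
            length(intersect(out$val, out$test)) == 0)
  out
}

#' Training configuration
#'
#' Defaults are the clinical-scale training settings: AdamW with weight decay
#' 0.1, learning rate 3e-5 for the baseline stage and 1e-4 for
#' fine-tuning, batches of 512 segments, a reduce-on-plateau scheduler
#' (patience 10, factor 0.5) and early stopping after 20 epochs without
#' validation improvement.
#'
#' @param stage `"baseline"` or `"finetune"`.
#' @param lr initial learning rate (stage-dependent default).
#' @param weight_decay decoupled weight decay coefficient.
#' @param batch_size segments per minibatch.
#' @param plateau_patience epochs without improvement before the learning
#'   rate is multiplied by `plateau_factor`.
#' @param plateau_factor learning-rate reduction factor.
#' @param early_stop_epochs epochs without validation improvement before
#'   training halts.
#' @param max_epochs hard epoch cap.
#' @param pos_weight positive-class weight in the loss (`NULL` = off).
#' @param augment an [augment_config()], or `NULL` to disable
#'   augmentation. Augmentation is applied to training batches only.
#' @param seed RNG seed for shuffling/augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(stage = c("baseline", "finetune"),
                         lr = NULL, weight_decay = 0.1, batch_size = 512,
                         plateau_patience = 10, plateau_factor = 0.5,
                         early_stop_epochs = 20, max_epochs = 100,
                         pos_weight = NULL, augment = augment_config(),
                         seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(lr)) lr <- if (stage == "baseline") 3e-5 else 1e-4
  structure(list(stage = stage, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 plateau_patience = plateau_patience,
                 plateau_factor = plateau_factor,
                 early_stop_epochs = early_stop_epochs,
                 max_epochs = max_epochs,
                 pos_weight = pos_weight, augment = augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- AdamW ---------------------------------------------------------------

trainable_names <- function(n_frozen) {
  blocks <- paste0("L", seq(n_frozen + 1, 8))
  c(unlist(lapply(blocks, function(b) paste0(b, ".", c("W", "b", "gamma",
                                                       "beta")))),
    "head_w", "head_b")
}

get_param <- function(model, name) {
  if (name == "head_w") return(model$head_w)
  if (name == "head_b") return(model$head_b)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  model$blocks[[parts[1]]][[parts[2]]]
}

set_param <- function(model, name, value) {
  if (name == "head_w") model$head_w <- value
  else if (name == "head_b") model$head_b <- value
  else {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    model$blocks[[parts[1]]][[parts[2]]] <- value
  }
  model
}

grad_of <- function(gr, name) {
  if (name == "head_w") return(gr$head_w)
  if (name == "head_b") return(gr$head_b)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  l <- as.integer(sub("^L", "", parts[1]))
  gr$grads[[l]][[parts[2]]]
}

adamw_init <- function(model, names) {
  st <- list(step = 0, m = list(), v = list())
  for (nm in names) {
    p <- get_param(model, nm)
    st$m[[nm]] <- p * 0
    st$v[[nm]] <- p * 0
  }
  st
}

# decoupled weight decay: decay is applied to the parameter directly,
# not through the gradient (weight decay exempts BN scale/shift and
# biases, the usual convention)
adamw_step <- function(model, gr, st, names, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  st$step <- st$step + 1
  bc1 <- 1 - beta1^st$step
  bc2 <- 1 - beta2^st$step
  for (nm in names) {
    g <- grad_of(gr, nm)
    p <- get_param(model, nm)
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    decay <- if (grepl("\\.(W)$", nm) || nm == "head_w") wd * p else 0
    model <- set_param(model, nm, p - lr * (upd + decay))
  }
  list(model = model, state = st)
}

# ---- training loop -------------------------------------------------------

# mean BCE-with-logits on a segment subset, evaluation mode
eval_loss <- function(model, X, y, pos_weight = 1, chunk = 256) {
  z <- forward_model(model, X, training = FALSE, chunk = chunk)
  w <- ifelse(y > 0.5, pos_weight, 1)
  mean(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z)))))
}

augment_batch <- function(xb, aug) {
  for (i in seq_len(dim(xb)[1]))
    xb[i, , ] <- augment_segment(xb[i, , ], aug)
  xb
}

#' Train a model on a fixed train/validation split
#'
#' Core loop shared by both stages: AdamW updates with optional
#' augmentation of training batches, per-epoch validation loss,
#' reduce-on-plateau scheduling and early stopping. The checkpoint with
#' the best validation loss is returned.
#'
#' @param model a `cnn_model` (fresh or a baseline checkpoint).
#' @param X segment array `[n x 19 x 2000]`.
#' @param y numeric 0/1 labels per segment.
#' @param train_idx,val_idx integer segment indices.
#' @param cfg a [train_config()].
#' @param n_frozen number of leading blocks to freeze (7 for the
#'   fine-tuning stage, 0 otherwise).
#' @return list with `model` (best checkpoint) and `history` (per-epoch
#'   data.frame: epoch, train_loss, val_loss, lr).
#' @export
fit_model <- function(model, X, y, train_idx, val_idx, cfg,
                      n_frozen = 0) {
  if (length(unique(y[train_idx])) < 2)
    stop("training labels are single-class; the loss is degenerate")
  pw <- if (is.null(cfg$pos_weight)) 1 else cfg$pos_weight
  names_tr <- trainable_names(n_frozen)
  st <- adamw_init(model, names_tr)
  lr <- cfg$lr
  best <- list(loss = Inf, model = model, epoch = 0)
  hist <- list()
  momentum <- 0.1
  with_local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      tl <- 0; nb <- 0
      for (i0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[i0:min(i0 + cfg$batch_size - 1, length(ord))]
        xb <- X[idx, , , drop = FALSE]
        if (!is.null(cfg$augment)) xb <- augment_batch(xb, cfg$augment)
        gr <- cnn_grad_cpp(model$blocks, model$head_w, model$head_b,
                           aperm(xb, c(2, 3, 1)), y[idx], pw,
                           as.integer(n_frozen), pooling_code(model))
        up <- adamw_step(model, gr, st, names_tr, lr, cfg$weight_decay)
        model <- up$model; st <- up$state
        # running BN statistics for the trainable blocks
        for (l in seq(n_frozen + 1, 8)) {
          bl <- paste0("L", l)
          model$blocks[[bl]]$running_mean <-
            (1 - momentum) * model$blocks[[bl]]$running_mean +
            momentum * gr$batch_mean[[l]]
          model$blocks[[bl]]$running_var <-
            (1 - momentum) * model$blocks[[bl]]$running_var +
            momentum * gr$batch_var[[l]]
        }
        tl <- tl + gr$loss; nb <- nb + 1
      }
      vl <- eval_loss(model, X[val_idx, , , drop = FALSE], y[val_idx], pw)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / nb,
                                  val_loss = vl, lr = lr)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, model = model, epoch = epoch)
      } else {
        since <- epoch - best$epoch
        if (since > 0 && since %% cfg$plateau_patience == 0)
          lr <- lr * cfg$plateau_factor
        if (since >= cfg$early_stop_epochs) break
      }
    }
  })
  list(model = best$model, history = do.call(rbind, hist),
       best_epoch = best$epoch)
}

# map each kept segment to its subject's label/arm
segment_subject <- function(segments) segments$index$subject_id

subset_kept <- function(segments) {
  which(segments$kept)
}

#' Two-stage cross-validated training
#'
#' For each of the `k` cross-validation iterations: trains the baseline
#' remission model on all training-fold subjects (both arms), fine-tunes
#' the placebo-response model on the placebo-arm subset with blocks
#' L1-L7 frozen, and predicts the test-fold segments with both models.
#' Across the rotation every subject is tested exactly once.
#'
#' @param segments a [segment_set()] for the whole cohort.
#' @param meta cohort metadata (columns `subject_id`, `arm`, `remission`,
#'   `responder`).
#' @param folds a [make_folds()] result.
#' @param spec a [model_spec()].
#' @param cfg_base,cfg_ft [train_config()]s for the two stages.
#' @param model_id identifier stamped on prediction rows.
#' @return list with `predictions` (data.frame: model_id, stage,
#'   subject_id, session_id, eye_state, segment_idx, logit, probability),
#'   `histories`, and `models` (per-iteration checkpoints).
#' @export
train_two_stage <- function(segments, meta, folds, spec = model_spec(),
                            cfg_base = train_config("baseline"),
                            cfg_ft = train_config("finetune"),
                            model_id = "m1") {
  kept <- subset_kept(segments)
  X <- segments$data[kept, , , drop = FALSE]
  idx <- segments$index[kept, , drop = FALSE]
  subj <- idx$subject_id
  meta_of <- meta[match(subj, meta$subject_id), ]
  y_rem <- as.numeric(meta_of$remission)
  y_resp <- as.numeric(meta_of$responder)
  placebo <- meta_of$arm == "placebo"

  preds <- list(); hists <- list(); models <- list()
  for (i in seq_len(folds$k) - 1L) {
    rot <- fold_rotation(folds, i)
    tr <- which(subj %in% rot$train)
    va <- which(subj %in% rot$val)
    te <- which(subj %in% rot$test)
    if (!length(te)) next
    m0 <- build_model(spec)
    base <- fit_model(m0, X, y_rem, tr, va, cfg_base, n_frozen = 0)
    tr_p <- tr[placebo[tr]]
    va_p <- va[placebo[va]]
    if (length(va_p) < 2) va_p <- va   # tiny-cohort fallback
    ft <- fit_model(base$model, X, y_resp, tr_p, va_p, cfg_ft,
                    n_frozen = 7)
    z_ft <- forward_model(ft$model, X[te, , , drop = FALSE])
    z_b <- forward_model(base$model, X[te, , , drop = FALSE])
    preds[[length(preds) + 1]] <- data.frame(
      model_id = model_id,
      stage = rep(c("finetune", "baseline"), each = length(te)),
      subject_id = rep(idx$subject_id[te], 2),
      session_id = rep(idx$session_id[te], 2),
      eye_state = rep(idx$eye_state[te], 2),
      segment_idx = rep(te, 2),
      logit = c(z_ft, z_b),
      probability = plogis(c(z_ft, z_b)),
      stringsAsFactors = FALSE)
    hists[[i + 1]] <- list(baseline = base$history, finetune = ft$history)
    models[[i + 1]] <- list(baseline = base$model, finetune = ft$model)
  }
  list(predictions = do.call(rbind, preds), histories = hists,
       models = models)
}

#' Single-stage placebo-only training (comparison arm)
#'
#' Trains the same architecture from scratch on the placebo-arm subjects
#' only, without remission pre-training; used as the comparison for the
#' two-stage pipeline.
#'
#' @inheritParams train_two_stage
#' @param cfg a [train_config()].
#' @return Prediction data.frame as in [train_two_stage()], stage
#'   `"single"`.
#' @export
train_single_stage <- function(segments, meta, folds, spec = model_spec(),
                               cfg = train_config("baseline"),
                               model_id = "m1") {
  kept <- subset_kept(segments)
  X <- segments$data[kept, , , drop = FALSE]
  idx <- segments$index[kept, , drop = FALSE]
  subj <- idx$subject_id
  meta_of <- meta[match(subj, meta$subject_id), ]
  y_resp <- as.numeric(meta_of$responder)
  placebo <- meta_of$arm == "placebo"
  preds <- list()
  for (i in seq_len(folds$k) - 1L) {
    rot <- fold_rotation(folds, i)
    tr <- which(subj %in% rot$train & placebo)
    va <- which(subj %in% rot$val & placebo)
    te <- which(subj %in% rot$test & placebo)
    if (!length(te)) next
    m0 <- build_model(spec)
    fit <- fit_model(m0, X, y_resp, tr, va, cfg, n_frozen = 0)
    z <- forward_model(fit$model, X[te, , , drop = FALSE])
    preds[[length(preds) + 1]] <- data.frame(
      model_id = model_id, stage = "single",
      subject_id = idx$subject_id[te], session_id = idx$session_id[te],
      eye_state = idx$eye_state[te], segment_idx = te,
      logit = z, probability = plogis(z), stringsAsFactors = FALSE)
  }
  do.call(rbind, preds)
}

#' Train an ensemble of independently split models
#'
#' Trains `n_models` two-stage models, each with its own random seed for
#' initialization/training and its own train-validation-test fold split,
#' so that ensemble variability reflects both initialization and
#' partitioning.
#'
#' @inheritParams train_two_stage
#' @param n_models ensemble size (20 at clinical scale).
#' @param base_seed seed from which per-model seeds are derived.
#' @return list with `predictions` (stacked prediction table) and
#'   `folds` (per-model fold splits).
#' @export
train_ensemble <- function(segments, meta, n_models = 20, base_seed = 1,
                           spec = model_spec(),
                           cfg_base = train_config("baseline"),
                           cfg_ft = train_config("finetune")) {
  preds <- list(); fsplits <- list()
  labels <- meta$responder[match(unique(segment_subject(segments)),
                                 meta$subject_id)]
  for (m in seq_len(n_models)) {
    sm <- base_seed + 7919L * m
    folds <- make_folds(unique(segment_subject(segments)), k = 5,
                        seed = sm, labels = labels)
    sp <- spec; sp$init_seed <- sm + 1L
    cb <- cfg_base; cb$seed <- sm + 2L
    cf <- cfg_ft; cf$seed <- sm + 3L
    run <- train_two_stage(segments, meta, folds, sp, cb, cf,
                           model_id = sprintf("m%02d", m))
    preds[[m]] <- run$predictions
    fsplits[[m]] <- folds
  }
  list(predictions = do.call(rbind, preds), folds = fsplits)
}
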