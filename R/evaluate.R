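# Ensemble aggregation and bootstrap metrics.
#
# Segment-level predictions from the model ensemble are averaged
# hierarchically (models -> segments -> sessions -> subjects) and the
# classification metrics are reported as mean +/- SD over a bootstrap that
# resamples the model axis per segment.

#' Tie-aware AUC by the rank statistic
#'
#' Area under the ROC curve computed from the Mann-Whitney rank form,
#' with midranks handling ties (all-equal scores give 0.5).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (logical or numeric).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.numeric(labels) > 0.5
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC is undefined with a single class")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at an operating threshold
#'
#' @param scores subject-level probabilities.
#' @param labels 0/1 subject labels (same order).
#' @param threshold operating point on the probability scale.
#' @return Named list: `loss` (binary cross-entropy computed from the
#'   logit of the score), `auc`, `bacc`, `sensitivity`, `specificity`,
#'   plus `precision`, `recall` and `f1`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels) > 0.5
  eps <- 1e-12
  p <- pmin(pmax(scores, eps), 1 - eps)
  loss <- -mean(labels * log(p) + (!labels) * log(1 - p))
  pred <- scores >= threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(loss = loss, auc = auc_rank(scores, labels),
       bacc = (sens + spec) / 2, sensitivity = sens, specificity = spec,
       precision = prec, recall = sens, f1 = f1,
       accuracy = mean(pred == labels))
}

# internal: segment/session/subject grouping keys from a prediction table
pred_keys <- function(preds) {
  seg_key <- paste(preds$subject_id, preds$session_id, preds$eye_state,
                   preds$segment_idx, sep = "\r")
  ses_key <- paste(preds$subject_id, preds$session_id, preds$eye_state,
                   sep = "\r")
  list(seg = seg_key, ses = ses_key, subj = preds$subject_id)
}

# hierarchical mean of a per-segment score vector: segments -> sessions
# -> subjects. seg_tab maps unique segments to their session/subject.
hier_mean <- function(seg_scores, seg_tab) {
  ses <- tapply(seg_scores, seg_tab$ses, mean)
  subj_of_ses <- seg_tab$subj[match(names(ses), seg_tab$ses)]
  out <- tapply(as.numeric(ses), subj_of_ses, mean)
  setNames(as.numeric(out), names(out))
}

#' Aggregate ensemble predictions to subject scores
#'
#' Hierarchical mean: per segment across models, per session across
#' segments, per subject across sessions.
#'
#' @param preds prediction table with columns `model_id`, `subject_id`,
#'   `session_id`, `eye_state`, `segment_idx`, `probability`.
#' @return Named numeric vector of subject scores in `[0, 1]`.
#' @export
aggregate_subject_scores <- function(preds) {
  if (!nrow(preds)) stop("empty prediction table")
  k <- pred_keys(preds)
  seg_scores <- tapply(preds$probability, k$seg, mean)
  first <- match(names(seg_scores), k$seg)
  seg_tab <- list(ses = k$ses[first], subj = k$subj[first])
  hier_mean(as.numeric(seg_scores), seg_tab)
}

#' Bootstrap ensemble metrics
#'
#' At each of `n_boot` repetitions, model predictions are drawn with
#' replacement (as many draws as there are models) independently for
#' every segment, averaged hierarchically into subject scores, and the
#' metric suite is computed at the operating threshold. Metrics are
#' reported as mean and SD over the bootstrap distribution.
#'
#' @param preds prediction table (one row per model x segment).
#' @param labels named 0/1 vector of subject labels.
#' @param n_boot bootstrap repetitions (1000 at clinical scale).
#' @param threshold operating threshold.
#' @param seed RNG seed.
#' @param unit `"model"` (default: resample the model axis per segment)
#'   or `"subject"` (resample subjects, a robustness variant).
#' @return list of per-metric `mean`/`sd` plus `n_boot`; class
#'   `metrics_report`.
#' @export
bootstrap_metrics <- function(preds, labels, n_boot = 1000,
                              threshold = 0.5, seed = 1,
                              unit = c("model", "subject")) {
  unit <- match.arg(unit)
  k <- pred_keys(preds)
  segs <- unique(k$seg)
  P <- matrix(NA_real_, length(unique(preds$model_id)), length(segs))
  rownames(P) <- unique(preds$model_id)
  colnames(P) <- segs
  P[cbind(match(preds$model_id, rownames(P)), match(k$seg, segs))] <-
    preds$probability
  first <- match(segs, k$seg)
  seg_tab <- list(ses = k$ses[first], subj = k$subj[first])
  subj_order <- unique(seg_tab$subj)
  y <- labels[subj_order]
  if (anyNA(y)) stop("labels missing for subject(s): ",
                     paste(subj_order[is.na(y)], collapse = ", "))
  if (length(unique(y)) < 2) stop("AUC is undefined with a single class")
  M <- nrow(P); S <- ncol(P)
  metric_names <- c("loss", "auc", "bacc", "sensitivity", "specificity")
  draws <- matrix(NA_real_, n_boot, length(metric_names),
                  dimnames = list(NULL, metric_names))
  with_local_seed(seed, {
    for (b in seq_len(n_boot)) {
      if (unit == "model") {
        idx <- matrix(sample.int(M, M * S, replace = TRUE), M, S)
        seg_scores <- colMeans(matrix(P[cbind(as.vector(idx),
                                              rep(seq_len(S), each = M))],
                                      M, S), na.rm = TRUE)
        sc <- hier_mean(seg_scores, seg_tab)
        yy <- y[names(sc)]
      } else {
        take <- sample(subj_order, length(subj_order), replace = TRUE)
        base_scores <- hier_mean(colMeans(P, na.rm = TRUE), seg_tab)
        sc <- base_scores[take]
        yy <- y[take]
      }
      if (length(unique(yy)) < 2) next
      m <- compute_metrics(sc, yy, threshold)
      draws[b, ] <- unlist(m[metric_names])
    }
  })
  out <- lapply(metric_names, function(nm)
    c(mean = mean(draws[, nm], na.rm = TRUE),
      sd = sd(draws[, nm], na.rm = TRUE)))
  names(out) <- metric_names
  out$n_boot <- n_boot
  structure(out, class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> bootstrap n =", x$n_boot, "\n")
  for (nm in c("loss", "auc", "bacc", "sensitivity", "specificity"))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", nm, x[[nm]]["mean"],
                x[[nm]]["sd"]))
  invisible(x)
}
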