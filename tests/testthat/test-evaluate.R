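# Subject-score aggregation, metric suite and ensemble bootstrap.

make_preds <- function(models, subjects, sessions, segs_per, prob_fun) {
  rows <- expand.grid(model_id = models, subject_id = subjects,
                      session_id = sessions, segment_idx = seq_len(segs_per),
                      stringsAsFactors = FALSE)
  rows$eye_state <- ifelse(rows$session_id == "sesEC", "EC", "EO")
  rows$probability <- prob_fun(rows)
  rows$logit <- qlogis(pmin(pmax(rows$probability, 1e-9), 1 - 1e-9))
  rows
}

test_that("aggregation is the hierarchical mean", {
  p <- make_preds("m1", c("a", "b"), c("sesEO", "sesEC"), 3,
                  function(r) rep(0.7, nrow(r)))
  expect_equal(unname(aggregate_subject_scores(p)), c(0.7, 0.7))
  # one subject, two sessions with means 0.2 and 0.8 -> 0.5
  p2 <- make_preds("m1", "a", c("sesEO", "sesEC"), 2,
                   function(r) ifelse(r$session_id == "sesEO", 0.2, 0.8))
  expect_equal(unname(aggregate_subject_scores(p2)), 0.5)
  # single model, single session: plain segment mean
  p3 <- make_preds("m1", "a", "sesEO", 4,
                   function(r) c(0.1, 0.2, 0.3, 0.8))
  expect_equal(unname(aggregate_subject_scores(p3)), mean(c(0.1, 0.2,
                                                            0.3, 0.8)))
  # permutation invariance in model order
  p4 <- make_preds(c("m1", "m2"), c("a", "b"), "sesEO", 3,
                   function(r) runif(nrow(r)))
  expect_equal(aggregate_subject_scores(p4),
               aggregate_subject_scores(p4[rev(seq_len(nrow(p4))), ]))
})

test_that("metrics match closed forms and conventions", {
  # all-equal scores: tie-aware AUC is 1/2
  expect_equal(auc_rank(rep(0.4, 6), c(1, 1, 0, 0, 1, 0)), 0.5)
  # cross-entropy at logits +/-1
  m <- compute_metrics(c(plogis(1), plogis(-1)), c(1, 0))
  expect_equal(m$loss, -log(plogis(1)), tolerance = 1e-9)
  # confusion-matrix counts on hand-set scores
  m2 <- compute_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$bacc, 1)
  expect_equal(m2$auc, 1)
  # single-class labels are refused
  expect_error(auc_rank(c(0.2, 0.4), c(1, 1)), "single class")
})

test_that("rank AUC equals brute-force pairwise concordance", {
  set.seed(7)
  for (rep_ in 1:5) {
    n <- 40
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(auc_rank(scores, labels),
                 conc / (length(pos) * length(neg)))
  }
})

test_that("bootstrap variance vanishes for identical models and separable scores", {
  subjects <- sprintf("s%d", 1:8)
  labs <- setNames(rep(c(1, 0), each = 4), subjects)
  p <- make_preds(sprintf("m%d", 1:5), subjects, "sesEO", 4,
                  function(r) ifelse(r$subject_id %in% subjects[1:4],
                                     0.9, 0.1))
  rep_ <- bootstrap_metrics(p, labs, n_boot = 50, seed = 3)
  expect_equal(unname(rep_$auc["mean"]), 1)
  expect_equal(unname(rep_$auc["sd"]), 0)
  expect_equal(unname(rep_$bacc["mean"]), 1)
  expect_equal(unname(rep_$sensitivity["sd"]), 0)
})

test_that("bootstrap means track the point estimate", {
  set.seed(11)
  subjects <- sprintf("s%02d", 1:30)
  labs <- setNames(rbinom(30, 1, 0.5), subjects)
  base <- setNames(0.35 + 0.3 * labs + rnorm(30, sd = 0.05), subjects)
  p <- make_preds(sprintf("m%02d", 1:10), subjects, "sesEO", 6,
                  function(r) pmin(pmax(base[r$subject_id] +
                                          rnorm(nrow(r), sd = 0.08),
                                        0.01), 0.99))
  point <- compute_metrics(aggregate_subject_scores(p), labs[subjects])
  rep_ <- bootstrap_metrics(p, labs, n_boot = 1000, seed = 5)
  for (nm in c("auc", "bacc")) {
    se <- rep_[[nm]]["sd"] / sqrt(1000)
    expect_lt(abs(rep_[[nm]]["mean"] - point[[nm]]),
              max(2 * se, 0.005))
  }
  # bacc is the mean of sensitivity and specificity, rep by rep
  expect_equal(unname(rep_$bacc["mean"]),
               unname((rep_$sensitivity["mean"] +
                         rep_$specificity["mean"]) / 2),
               tolerance = 1e-12)
})

test_that("balanced accuracy is invariant to relabeling subject ids", {
  set.seed(2)
  subjects <- sprintf("s%d", 1:10)
  labs <- setNames(rep(c(1, 0), 5), subjects)
  p <- make_preds("m1", subjects, "sesEO", 3,
                  function(r) runif(nrow(r)))
  sc <- aggregate_subject_scores(p)
  m1 <- compute_metrics(sc, labs[names(sc)])
  ren <- setNames(sprintf("t%d", 1:10), subjects)
  p2 <- p; p2$subject_id <- ren[p2$subject_id]
  sc2 <- aggregate_subject_scores(p2)
  labs2 <- setNames(labs, ren[names(labs)])
  m2 <- compute_metrics(sc2, labs2[names(sc2)])
  expect_equal(m1$bacc, m2$bacc)
})
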