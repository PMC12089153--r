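# Classifier: construction, forward contract, gradients, freezing,
# throughput.

test_that("build exposes named blocks L1..L8 plus head, deterministically", {
  m1 <- build_model(tiny_spec())
  m2 <- build_model(tiny_spec())
  expect_equal(names(m1$blocks), paste0("L", 1:8))
  expect_identical(m1$blocks, m2$blocks)
  expect_identical(m1$head_w, m2$head_w)
  m3 <- build_model(tiny_spec(init_seed = 3))
  expect_false(identical(m1$blocks$L1$W, m3$blocks$L1$W))
})

test_that("temporal geometry survives the stride cascade", {
  # stride-arithmetic oracle: same-padded conv of length L with stride s
  # gives floor((L - 1) / s) + 1 samples
  spec <- model_spec()
  len <- spec$in_len
  for (l in 1:8) len <- floor((len - 1) / spec$strides[l]) + 1
  expect_gte(len, 1)
  m <- build_model(spec)
  z <- forward_model(m, array(rnorm(19 * 2000), c(1, 19, 2000)))
  expect_true(is.finite(z))
  expect_error(model_spec(channels = c(8, 8, 16)), "8 convolutional")
})

test_that("forward contract: zero head, duplicated rows, batch sizing, shapes", {
  m <- build_model(tiny_spec())
  b <- tiny_batch()
  mz <- m; mz$head_w[] <- 0; mz$head_b <- 0
  expect_equal(forward_model(mz, b$X), rep(0, 6))
  expect_equal(predict_proba(mz, b$X), rep(0.5, 6))
  # duplicated inputs give identical logits in evaluation mode
  Xd <- b$X[c(1, 1, 2), , , drop = FALSE]
  z <- forward_model(m, Xd)
  expect_identical(z[1], z[2])
  # one logit per segment at large batch
  Xl <- array(rnorm(512 * 4 * 40), c(512, 4, 40))
  expect_length(forward_model(m, Xl), 512)
  # wrong shape errors name the expected layout
  bad <- array(rnorm(2 * 5 * 40), c(2, 5, 40))
  expect_error(forward_model(m, bad), "\\[4 x 40\\]")
})

test_that("probabilities match the closed-form sigmoid", {
  m <- build_model(tiny_spec())
  b <- tiny_batch()
  z <- forward_model(m, b$X)
  expect_equal(predict_proba(m, b$X), 1 / (1 + exp(-z)),
               tolerance = 1e-12)
})

test_that("analytic gradients match a directional finite difference", {
  m <- build_model(tiny_spec())
  b <- tiny_batch(n = 8)
  cube <- aperm(b$X, c(2, 3, 1))
  g <- placeboeeg:::cnn_grad_cpp(m$blocks, m$head_w, m$head_b, cube,
                                 b$y, 1.0, 0L, 0L)
  set.seed(9)
  dirs <- list()
  for (l in 1:8) for (f in c("W", "b", "gamma", "beta")) {
    v <- m$blocks[[l]][[f]]
    d <- rnorm(length(v)); dim(d) <- dim(v)
    dirs[[paste0(l, f)]] <- d
  }
  dirs$hw <- rnorm(length(m$head_w)); dirs$hb <- rnorm(1)
  perturb <- function(m, eps) {
    gd <- 0
    for (l in 1:8) for (f in c("W", "b", "gamma", "beta")) {
      d <- dirs[[paste0(l, f)]]
      m$blocks[[l]][[f]] <- m$blocks[[l]][[f]] + eps * d
      gd <- gd + sum(g$grads[[l]][[f]] * d)
    }
    m$head_w <- m$head_w + eps * dirs$hw
    m$head_b <- m$head_b + eps * dirs$hb
    list(m = m, gd = gd + sum(g$head_w * dirs$hw) + g$head_b * dirs$hb)
  }
  eps <- 1e-3
  up <- perturb(m, eps); dn <- perturb(m, -eps)
  lo <- function(mm) placeboeeg:::cnn_grad_cpp(mm$blocks, mm$head_w,
                                               mm$head_b, cube, b$y, 1.0,
                                               0L, 0L)$loss
  num <- (lo(up$m) - lo(dn$m)) / (2 * eps)
  expect_equal(num, up$gd, tolerance = 0.02)
})

test_that("a fine-tuning step changes only L8 and the head, bitwise", {
  m <- build_model(tiny_spec())
  b <- tiny_batch(n = 12)
  cfg <- train_config("finetune", batch_size = 6, max_epochs = 1,
                      early_stop_epochs = 1, augment = NULL, seed = 2)
  fit <- fit_model(m, b$X, b$y, train_idx = 1:8, val_idx = 9:12, cfg,
                   n_frozen = 7)
  expect_true(placeboeeg:::params_identical(m, fit$model, paste0("L", 1:7)))
  expect_false(placeboeeg:::params_identical(m, fit$model, "L8"))
  expect_false(identical(m$head_w, fit$model$head_w))
  # frozen batch-norm buffers are untouched as well
  for (l in 1:7) {
    expect_identical(m$blocks[[l]]$running_mean,
                     fit$model$blocks[[l]]$running_mean)
    expect_identical(m$blocks[[l]]$running_var,
                     fit$model$blocks[[l]]$running_var)
  }
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny_spec())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_identical(back$blocks, m$blocks)
  unlink(c(path, paste0(path, ".json")))
})

test_that("one training epoch over 5000 segments stays under a minute", {
  set.seed(1)
  m <- build_model(model_spec())
  pool <- array(rnorm(500 * 19 * 2000, sd = 10), c(19, 2000, 500))
  y <- rbinom(128, 1, 0.5)
  n <- 5000
  t0 <- Sys.time()
  done <- 0
  while (done < n) {
    b <- min(128, n - done)
    take <- (done + seq_len(b) - 1) %% 500 + 1
    placeboeeg:::cnn_grad_cpp(m$blocks, m$head_w, m$head_b,
                              pool[, , take, drop = FALSE], y[seq_len(b)],
                              1.0, 0L, 0L)
    done <- done + b
  }
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})
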