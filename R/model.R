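# Eight-block 1-D convolutional classifier.
#
# Convolutions run over time with the 19 electrodes as input channels;
# each block is convolution -> batch normalization -> ReLU. A pooling
# stage (global average by default, adaptive max available) collapses the
# temporal axis and a linear head maps the pooled feature vector to a
# single placebo-response logit per segment.

#' Specify the classifier architecture
#'
#' @param channels output channels of blocks L1..L8. The default
#'   progression is sized so that a full training epoch is practical on a
#'   single CPU; widths are freely overridable.
#' @param kernel convolution kernel length(s) in samples: either one
#'   value shared by all blocks or a vector of 8. A long first kernel
#'   (order of an oscillation period) helps the first block learn
#'   band-selective filters from raw traces.
#' @param strides per-block temporal strides; the default halves the
#'   temporal axis at every even block (2000 -> 125 samples at L8).
#' @param pooling `"global_average"` or `"adaptive_max"`.
#' @param in_channels input channel count (the 19-electrode montage).
#' @param in_len input segment length in samples.
#' @param init_seed seed for weight initialization.
#' @return A validated `model_spec` list.
#' @export
model_spec <- function(channels = c(8, 8, 16, 16, 32, 32, 64, 64),
                       kernel = 7,
                       strides = rep(c(1, 2), 4),
                       pooling = c("global_average", "adaptive_max"),
                       in_channels = 19, in_len = 2000,
                       init_seed = 1L) {
  pooling <- match.arg(pooling)
  if (length(channels) != 8 || length(strides) != 8)
    stop("the architecture has exactly 8 convolutional blocks; got ",
         length(channels), " channel widths and ", length(strides),
         " strides")
  if (length(kernel) == 1) kernel <- rep(kernel, 8)
  if (length(kernel) != 8)
    stop("kernel must be one length or one per block")
  stopifnot(all(channels >= 1), all(strides >= 1), all(kernel >= 1))
  # validate temporal geometry: length must stay >= 1 through all strides
  len <- in_len
  for (l in 1:8) {
    len <- floor((len + 2 * (kernel[l] %/% 2) - kernel[l]) / strides[l]) + 1
    if (len < 1)
      stop("temporal length collapses to ", len, " at block L", l,
           "; reduce strides for a ", in_len, "-sample input")
  }
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 strides = as.integer(strides), pooling = pooling,
                 in_channels = as.integer(in_channels),
                 in_len = as.integer(in_len),
                 init_seed = as.integer(init_seed)),
            class = "model_spec")
}

#' Build a classifier with freshly initialized weights
#'
#' He-normal convolution weights, unit-gain batch-norm parameters and a
#' small-normal head. Two builds from the same spec and seed are
#' identical. Parameter groups are named `L1`..`L8` and `head` so that
#' layers are individually addressable for freezing.
#'
#' @param spec a [model_spec()].
#' @return An object of class `cnn_model`.
#' @export
build_model <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  with_local_seed(spec$init_seed, {
    in_ch <- spec$in_channels
    blocks <- vector("list", 8)
    names(blocks) <- paste0("L", 1:8)
    for (l in 1:8) {
      out_ch <- spec$channels[l]
      fan_in <- in_ch * spec$kernel[l]
      blocks[[l]] <- list(
        W = matrix(rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)),
                   out_ch, fan_in),
        b = rep(0, out_ch),
        gamma = rep(1, out_ch),
        beta = rep(0, out_ch),
        running_mean = rep(0, out_ch),
        running_var = rep(1, out_ch),
        stride = spec$strides[l],
        kernel = spec$kernel[l])
      in_ch <- out_ch
    }
    structure(list(spec = spec, blocks = blocks,
                   head_w = rnorm(spec$channels[8], sd = 0.01),
                   head_b = 0),
              class = "cnn_model")
  })
}

#' @exportS3Method base::print
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> 8 conv blocks (conv-BN-ReLU), pooling:",
      x$spec$pooling, "\n")
  cat("  widths:", paste(x$spec$channels, collapse = "-"),
      " kernels:", paste(x$spec$kernel, collapse = "-"),
      " strides:", paste(x$spec$strides, collapse = ""), "\n")
  cat("  parameters:", model_n_params(x), "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model a [build_model()] result.
#' @return Integer count over L1..L8 and the head.
#' @export
model_n_params <- function(model) {
  n <- length(model$head_w) + 1
  for (bl in model$blocks)
    n <- n + length(bl$W) + length(bl$b) + length(bl$gamma) +
      length(bl$beta)
  n
}

pooling_code <- function(model) {
  if (model$spec$pooling == "global_average") 0L else 1L
}

# [B x C x T] array (or [C x T] matrix) -> C x T x B cube
batch_to_cube <- function(model, batch) {
  if (is.matrix(batch)) batch <- array(batch, c(1, dim(batch)))
  d <- dim(batch)
  if (length(d) != 3 || d[2] != model$spec$in_channels ||
      d[3] != model$spec$in_len)
    stop("expected a batch of segments shaped [", model$spec$in_channels,
         " x ", model$spec$in_len, "]; got [", d[2], " x ", d[3], "]")
  aperm(batch, c(2, 3, 1))
}

#' Forward pass: segments to logits
#'
#' @param model a `cnn_model`.
#' @param batch numeric array `[B x 19 x 2000]` (or a single `[19 x 2000]`
#'   matrix).
#' @param training if `TRUE`, batch normalization uses minibatch
#'   statistics; in evaluation mode (default) the stored running
#'   statistics are used and the output is deterministic for fixed
#'   weights.
#' @param chunk maximum segments processed per internal batch.
#' @return Numeric vector of logits, one per segment.
#' @export
forward_model <- function(model, batch, training = FALSE, chunk = 256) {
  x <- batch_to_cube(model, batch)
  B <- dim(x)[3]
  out <- numeric(B)
  for (i0 in seq(1, B, by = chunk)) {
    i1 <- min(i0 + chunk - 1, B)
    out[i0:i1] <- cnn_forward_cpp(model$blocks, model$head_w, model$head_b,
                                  x[, , i0:i1, drop = FALSE], training,
                                  pooling_code(model))
  }
  out
}

#' Predicted placebo-response probabilities
#'
#' `sigmoid(logit)`, elementwise.
#'
#' @inheritParams forward_model
#' @return Probabilities in (0, 1), one per segment.
#' @export
predict_proba <- function(model, batch, ...) {
  plogis(forward_model(model, batch, ...))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is R's native serialization of the full model; a JSON
#' sidecar (`<path>.json`) carries the architecture spec for inspection.
#'
#' @param model a `cnn_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$spec[names(model$spec) != "class"],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}

# deep parameter equality between two models over a set of block names
params_identical <- function(m1, m2, block_names) {
  for (nm in block_names) {
    for (f in c("W", "b", "gamma", "beta")) {
      if (!identical(m1$blocks[[nm]][[f]], m2$blocks[[nm]][[f]]))
        return(FALSE)
    }
  }
  TRUE
}
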