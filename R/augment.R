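# Stochastic training-time augmentation.
#
# Five operators applied to [19 x 2000] training segments (never to
# validation or test segments): random-channel re-referencing, additive
# Gaussian noise, single-channel amplitude amplification, time reversal
# and horizontal compression with zero padding. All draws come from R's
# RNG so a seeded augmentation stream is reproducible bit for bit.

#' Augmentation configuration
#'
#' @param noise_sd_max upper bound of the uniform draw for the additive
#'   noise SD, in units of each channel's own standard deviation
#'   (scale-free).
#' @param amp_max upper bound of the uniform amplitude gain for the
#'   amplified channel (>= 1).
#' @param scale_min lower bound of the horizontal compression factor, in
#'   (0, 1].
#' @param p named per-operator application probabilities.
#' @return Validated list of class `augment_config`.
#' @export
augment_config <- function(noise_sd_max = 0.2, amp_max = 1.2,
                           scale_min = 0.5,
                           p = c(rereference = 0.5, noise = 0.5,
                                 amplify = 0.5, flip = 0.5, scale = 0.5)) {
  stopifnot(noise_sd_max >= 0, amp_max >= 1,
            scale_min > 0, scale_min <= 1,
            all(p >= 0 & p <= 1))
  structure(list(noise_sd_max = noise_sd_max, amp_max = amp_max,
                 scale_min = scale_min, p = p), class = "augment_config")
}

#' Re-reference a segment to a random channel
#'
#' Subtracts one randomly chosen channel from every channel; the chosen
#' channel's row becomes zero and channel-pair differences are unchanged.
#'
#' @param seg numeric matrix `[n_channels x n_samples]`.
#' @param channel reference channel index; drawn uniformly when `NULL`.
#' @return The re-referenced segment, with the chosen index in attribute
#'   `"reference"`.
#' @export
aug_rereference <- function(seg, channel = NULL) {
  if (is.null(channel)) channel <- sample.int(nrow(seg), 1)
  out <- sweep(seg, 2, seg[channel, ], "-")
  attr(out, "reference") <- channel
  out
}

#' Add Gaussian noise to a segment
#'
#' Noise SD is drawn uniformly from `[0, noise_sd_max]` and applied in
#' units of each channel's standard deviation, so the perturbation is
#' scale-free across recordings of different amplitude.
#'
#' @param seg segment matrix.
#' @param cfg an [augment_config()].
#' @param sd_frac force the drawn SD fraction (testing hook).
#' @return The noisy segment.
#' @export
aug_noise <- function(seg, cfg = augment_config(), sd_frac = NULL) {
  if (is.null(sd_frac)) sd_frac <- runif(1, 0, cfg$noise_sd_max)
  if (sd_frac == 0) return(seg)
  ch_sd <- apply(seg, 1, sd)
  seg + matrix(rnorm(length(seg)), nrow(seg)) * (ch_sd * sd_frac)
}

#' Amplify one random channel
#'
#' @param seg segment matrix.
#' @param cfg an [augment_config()].
#' @param channel,factor force the drawn channel/gain (testing hooks).
#' @return The segment with one channel scaled by a factor in
#'   `[1, amp_max]`; all other channels bitwise unchanged.
#' @export
aug_amplify <- function(seg, cfg = augment_config(), channel = NULL,
                        factor = NULL) {
  if (is.null(channel)) channel <- sample.int(nrow(seg), 1)
  if (is.null(factor)) factor <- runif(1, 1, cfg$amp_max)
  seg[channel, ] <- seg[channel, ] * factor
  attr(seg, "amplified") <- c(channel = channel, factor = factor)
  seg
}

#' Reverse the time axis of a segment
#'
#' @param seg segment matrix.
#' @return The time-reversed segment (an involution).
#' @export
aug_flip <- function(seg) {
  seg[, rev(seq_len(ncol(seg))), drop = FALSE]
}

# Fourier-domain resampling to an arbitrary length: exact for
# band-limited signals and cheap enough for per-batch augmentation.
resample_fft <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(m)
  half <- floor(min(n, m) / 2)
  Y[1] <- X[1]
  if (half > 1) {
    k <- seq_len(half - 1)
    Y[k + 1] <- X[k + 1]
    Y[m - k + 1] <- X[n - k + 1]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Compress a segment along time and zero-pad back
#'
#' Resamples every channel to `round(n * f)` samples (Fourier-domain
#' resampling), `f` drawn uniform in `[scale_min, 1]`, and appends zeros
#' to restore the original length.
#'
#' @param seg segment matrix.
#' @param cfg an [augment_config()].
#' @param factor force the drawn compression factor (testing hook).
#' @return The compressed-and-padded segment, same shape as the input.
#' @export
aug_scale <- function(seg, cfg = augment_config(), factor = NULL) {
  if (is.null(factor)) factor <- runif(1, cfg$scale_min, 1)
  n <- ncol(seg)
  m <- round(n * factor)
  if (m == n) return(seg)
  out <- matrix(0, nrow(seg), n)
  for (i in seq_len(nrow(seg)))
    out[i, seq_len(m)] <- resample_fft(seg[i, ], m)
  rownames(out) <- rownames(seg)
  out
}

#' Apply the augmentation pipeline to one segment
#'
#' Each operator is applied independently with its configured probability.
#' With all probabilities zero this is the identity.
#'
#' @param seg segment matrix `[n_channels x n_samples]`.
#' @param cfg an [augment_config()].
#' @return The augmented segment.
#' @export
augment_segment <- function(seg, cfg = augment_config()) {
  if (runif(1) < cfg$p[["rereference"]]) seg <- aug_rereference(seg)
  if (runif(1) < cfg$p[["noise"]]) seg <- aug_noise(seg, cfg)
  if (runif(1) < cfg$p[["amplify"]]) seg <- aug_amplify(seg, cfg)
  if (runif(1) < cfg$p[["flip"]]) seg <- aug_flip(seg)
  if (runif(1) < cfg$p[["scale"]]) seg <- aug_scale(seg, cfg)
  attributes(seg)[c("reference", "amplified")] <- NULL
  dimnames(seg) <- NULL
  seg
}
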