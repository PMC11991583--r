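#' Sigmoid-weighted linear unit (SiLU)
#'
#' Elementwise activation \eqn{f(x) = x \cdot \sigma(x)} where \eqn{\sigma}
#' is the logistic sigmoid. Used throughout the SeCUIB expansion and
#' depthwise stages.
#'
#' @param x numeric vector or array.
#' @return object of the same shape as `x`.
#' @export
#' @examples
#' silu(0)      # 0
#' silu(1)      # 0.731059
silu <- function(x) x * stats::plogis(x)

#' @keywords internal
siluGrad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

#' @keywords internal
sigmoid <- function(x) stats::plogis(x)

#' Channel shuffle permutation
#'
#' Interleaves channels across convolution groups by the
#' reshape-transpose-flatten permutation: channels viewed as a
#' `groups x (C/groups)` table are read column-wise. Spatial content is
#' untouched and the operation is invertible (see [channelUnshuffle()]).
#'
#' @param x feature map, array `[N, C, H, W]`.
#' @param groups number of groups; `C` must be divisible by `groups`.
#' @return array of the same shape with channels permuted.
#' @export
channelShuffle <- function(x, groups) {
  C <- dim(x)[2]
  x[, shufflePermutation(C, groups), , , drop = FALSE]
}

#' @rdname channelShuffle
#' @export
channelUnshuffle <- function(x, groups) {
  C <- dim(x)[2]
  x[, order(shufflePermutation(C, groups)), , , drop = FALSE]
}

#' @keywords internal
shufflePermutation <- function(C, groups) {
  if (C %% groups != 0)
    stop("channel count ", C, " not divisible by shuffle groups ", groups)
  as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
}

#' Batch normalization transform
#'
#' Per-channel affine normalization
#' \eqn{\hat{x} = (x - \mu)/\sqrt{\sigma^2 + \epsilon} \cdot \gamma + \beta}.
#' This is the pure transform given fixed statistics; training-time batch
#' statistics are handled inside the network layers.
#'
#' @param x feature map `[N, C, H, W]`.
#' @param mean,var per-channel mean and variance vectors (length `C`).
#' @param gamma,beta per-channel scale and shift (length `C`).
#' @param eps small positive stabilizer.
#' @return normalized array, same shape as `x`.
#' @export
batchNorm <- function(x, mean, var, gamma, beta, eps = 1e-3) {
  stopifnot(all(var >= 0), eps >= 0)
  N <- dim(x)[1]
  sc <- gamma / sqrt(var + eps)
  x * rep(sc, each = N) + rep(beta - mean * sc, each = N)
}

#' Initialize squeeze-excitation gate weights
#'
#' Two-layer bottleneck: reduce `channels` to `max(1, round(channels * ratio))`,
#' ReLU, expand back, sigmoid. Both linear maps carry biases.
#'
#' @param channels number of input channels.
#' @param ratio reduction ratio in (0, 1].
#' @param init `"kaiming"` for random scaled-normal weights, `"zero"` for all
#'   zeros (gates at 0.5).
#' @return list with `W1`, `b1`, `W2`, `b2`.
#' @export
seInit <- function(channels, ratio = 0.25, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  r <- max(1L, round(channels * ratio))
  if (init == "zero") {
    list(W1 = matrix(0, channels, r), b1 = numeric(r),
         W2 = matrix(0, r, channels), b2 = numeric(channels))
  } else {
    list(W1 = matrix(stats::rnorm(channels * r, sd = sqrt(2 / channels)), channels, r),
         b1 = numeric(r),
         W2 = matrix(stats::rnorm(r * channels, sd = sqrt(2 / r)), r, channels),
         b2 = numeric(channels))
  }
}

#' Squeeze-excitation channel gating
#'
#' Computes a per-channel gate in (0, 1) from the global spatial mean of the
#' input through a two-layer bottleneck (reduce, ReLU, expand, sigmoid) and
#' rescales each channel by its gate.
#'
#' @param x feature map `[N, C, H, W]`.
#' @param weights gate parameters as produced by [seInit()].
#' @return gated feature map, same shape as `x`.
#' @export
squeezeExcite <- function(x, weights) {
  d <- dim(x)
  N <- d[1]; C <- d[2]
  p <- matrix(rowMeans(matrix(x, nrow = N * C)), N, C)
  h <- pmax(sweep(p %*% weights$W1, 2, weights$b1, "+"), 0)
  g <- sigmoid(sweep(h %*% weights$W2, 2, weights$b2, "+"))
  x * as.vector(g)
}
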