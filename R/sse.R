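#' Create (seeded) weights for the spatial squeeze-and-excitation module
#'
#' The SSE module has two branches applied in sequence: a channel
#' squeeze-and-excitation (SE) block — global average pooling, a two-layer
#' bottleneck network with reduction ratio `r`, sigmoid gates — followed by
#' a spatial attention branch that reduces the recalibrated map along the
#' channel axis with max and mean pooling, stacks the two descriptors, and
#' passes them through a `k x k` convolution and a sigmoid. This constructor
#' builds the explicit, inspectable parameter set for a given channel count.
#'
#' Weights are drawn uniformly from `[-1/sqrt(fan_in), +1/sqrt(fan_in)]`
#' under the given seed; biases start at zero. No training is performed in
#' this package — the weights exist so the forward computation can be
#' exercised and verified.
#'
#' @param channels Number of input channels `C`.
#' @param r Reduction ratio of the SE bottleneck (default 16; the bottleneck
#'   width is `max(1, floor(C / r))`).
#' @param k Spatial kernel size; must be odd so zero padding `(k - 1)/2`
#'   preserves the spatial size. Default 7, the configuration found best;
#'   3, 5, 9 and 11 are also sensible.
#' @param seed Optional integer seed for reproducible initialization.
#' @return A list of class `"sse_weights"` with elements `W1` (`Cb x C`),
#'   `b1` (`Cb`), `W2` (`C x Cb`), `b2` (`C`), `spatial_kernel`
#'   (`1 x 2 x k x k` array; input channels ordered `[max_out, avg_out]`),
#'   `spatial_bias` (scalar), `r`, `k`, `channels`, `seed`.
#' @examples
#' w <- sse_weights(8, r = 4, k = 3, seed = 1)
#' @export
sse_weights <- function(channels, r = 16, k = 7, seed = NULL) {
  stopifnot(channels >= 1, r >= 1)
  if (k %% 2 == 0) stop("spatial kernel size k must be odd", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cb <- max(1L, channels %/% r)
  u <- function(n, fan_in) stats::runif(n, -1 / sqrt(fan_in), 1 / sqrt(fan_in))
  structure(list(
    W1 = matrix(u(cb * channels, channels), nrow = cb),
    b1 = numeric(cb),
    W2 = matrix(u(channels * cb, cb), nrow = channels),
    b2 = numeric(channels),
    spatial_kernel = array(u(2 * k * k, 2 * k * k), dim = c(1, 2, k, k)),
    spatial_bias = 0,
    r = r, k = k, channels = channels, seed = seed
  ), class = "sse_weights")
}

#' @export
print.sse_weights <- function(x, ...) {
  cat(sprintf("<sse_weights> C = %d, bottleneck = %d (r = %d), spatial kernel %dx%d\n",
              x$channels, length(x$b1), x$r, x$k, x$k))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

check_feature_map <- function(X) {
  if (!is.array(X) || length(dim(X)) != 4) {
    stop("feature map must be a 4-d array with dim (B, C, H, W)", call. = FALSE)
  }
  if (!all(is.finite(X))) stop("feature map contains non-finite values", call. = FALSE)
  invisible(dim(X))
}

#' Global average pooling over the spatial axes
#'
#' Squeeze step of the SE block: each channel of each batch element is
#' summarized by the mean of its `H x W` activations.
#'
#' @param X A `B x C x H x W` array.
#' @return A `B x C` matrix of channel descriptors `z`.
#' @export
global_avg_pool <- function(X) {
  d <- check_feature_map(X)
  # mean over dims 3:4; rowMeans on the (B*C) x (H*W) reshape
  z <- rowMeans(matrix(X, nrow = d[1] * d[2]))
  matrix(z, nrow = d[1], ncol = d[2])
}

#' Channel excitation: bottleneck network and sigmoid gates
#'
#' Excitation step of the SE block:
#' `y = sigmoid(W2 %*% relu(W1 %*% z + b1) + b2)` applied independently per
#' batch element. Every gate lies strictly in (0, 1) for finite inputs.
#'
#' @param z `B x C` matrix of channel descriptors (or length-C vector for a
#'   single batch element).
#' @param weights An [sse_weights()] object (or a list providing
#'   `W1, b1, W2, b2`).
#' @return `B x C` matrix of channel weights `y`.
#' @export
channel_excitation <- function(z, weights) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  C <- ncol(z)
  if (ncol(weights$W1) != C) {
    stop(sprintf("W1 has %d columns but z has %d channels",
                 ncol(weights$W1), C), call. = FALSE)
  }
  if (nrow(weights$W2) != C || ncol(weights$W2) != nrow(weights$W1)) {
    stop(sprintf("W2 must be %d x %d, got %d x %d",
                 C, nrow(weights$W1), nrow(weights$W2), ncol(weights$W2)),
         call. = FALSE)
  }
  a <- z %*% t(weights$W1)                      # B x Cb
  a <- sweep(a, 2, weights$b1, "+")
  a[a < 0] <- 0                                 # ReLU
  y <- a %*% t(weights$W2)                      # B x C
  y <- sweep(y, 2, weights$b2, "+")
  sigmoid(y)
}

#' Recalibrate channels by elementwise gating
#'
#' `X'[b, c, i, j] = y[b, c] * X[b, c, i, j]`.
#'
#' @param X A `B x C x H x W` array.
#' @param y `B x C` matrix of channel gates.
#' @return Array of the same shape as `X`.
#' @export
channel_recalibrate <- function(X, y) {
  d <- check_feature_map(X)
  if (is.null(dim(y))) y <- matrix(y, nrow = d[1])
  stopifnot(nrow(y) == d[1], ncol(y) == d[2])
  # (B, C) varies fastest in the first two dims, so plain recycling works
  X * as.vector(y)
}

# 2-d cross-correlation with zero padding (k-1)/2, stride 1.
conv2d_same <- function(x, kern, bias = 0) {
  k <- nrow(kern)
  p <- (k - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  xp <- matrix(0, H + 2 * p, W + 2 * p)
  xp[p + seq_len(H), p + seq_len(W)] <- x
  out <- matrix(bias, H, W)
  for (u in seq_len(k)) {
    for (v in seq_len(k)) {
      out <- out + kern[u, v] * xp[u:(u + H - 1), v:(v + W - 1)]
    }
  }
  out
}

#' Spatial attention map from channel-pooled descriptors
#'
#' Reduces the (channel-recalibrated) feature map along the channel axis
#' with max and mean pooling, then applies a `k x k` convolution
#' (cross-correlation, stride 1, zero padding `(k-1)/2`) to the stacked
#' two-channel descriptor and a sigmoid, yielding one `H x W` attention map
#' per batch element.
#'
#' @param Xp A `B x C x H x W` array (typically the SE-recalibrated map).
#' @param kernel `1 x 2 x k x k` array; input channel 1 convolves `max_out`,
#'   channel 2 convolves `avg_out`.
#' @param bias Scalar added before the sigmoid.
#' @return A list with `max_out`, `avg_out` and `S`, each a `B x H x W`
#'   array; every element of `S` lies strictly in (0, 1).
#' @export
spatial_attention_map <- function(Xp, kernel, bias = 0) {
  d <- check_feature_map(Xp)
  kd <- dim(kernel)
  if (length(kd) != 4 || kd[1] != 1 || kd[2] != 2 || kd[3] != kd[4]) {
    stop("spatial kernel must have dim (1, 2, k, k)", call. = FALSE)
  }
  if (kd[3] %% 2 == 0) stop("spatial kernel size k must be odd", call. = FALSE)
  B <- d[1]; H <- d[3]; W <- d[4]
  max_out <- array(0, dim = c(B, H, W))
  avg_out <- array(0, dim = c(B, H, W))
  S <- array(0, dim = c(B, H, W))
  for (b in seq_len(B)) {
    slab <- array(Xp[b, , , ], dim = d[2:4])      # C x H x W
    mo <- apply(slab, c(2, 3), max)
    ao <- apply(slab, c(2, 3), mean)
    pre <- conv2d_same(mo, kernel[1, 1, , ]) +
      conv2d_same(ao, kernel[1, 2, , ]) + bias
    max_out[b, , ] <- mo
    avg_out[b, , ] <- ao
    S[b, , ] <- sigmoid(pre)
  }
  list(max_out = max_out, avg_out = avg_out, S = S)
}

#' Full SSE forward pass
#'
#' Applies the channel SE branch first and then computes the spatial
#' attention map on the recalibrated features, gating them a second time:
#' `O[b, c, i, j] = X'[b, c, i, j] * S[b, i, j]` with
#' `X' = y * X`. Both gates lie in (0, 1), so `|O| <= |X|` elementwise.
#'
#' @param X A `B x C x H x W` array.
#' @param weights An [sse_weights()] object matching `C`.
#' @return A list of class `"sse_attention"` with `z` (`B x C`), `y`
#'   (`B x C`), `Xp`, `max_out`, `avg_out`, `S`, `O` and the `weights`
#'   used. `O` has exactly the input's shape.
#' @examples
#' X <- gen_feature_map(1, 4, 5, 5, seed = 1)
#' out <- sse_forward(X, sse_weights(4, r = 2, k = 3, seed = 2))
#' dim(out$O)
#' @export
sse_forward <- function(X, weights) {
  d <- check_feature_map(X)
  if (weights$channels != d[2]) {
    stop(sprintf("weights built for %d channels but input has %d",
                 weights$channels, d[2]), call. = FALSE)
  }
  z <- global_avg_pool(X)
  y <- channel_excitation(z, weights)
  Xp <- channel_recalibrate(X, y)
  sp <- spatial_attention_map(Xp, weights$spatial_kernel, weights$spatial_bias)
  O <- Xp
  for (cc in seq_len(d[2])) {
    O[, cc, , ] <- array(Xp[, cc, , ], dim = d[c(1, 3, 4)]) * sp$S
  }
  structure(list(z = z, y = y, Xp = Xp, max_out = sp$max_out,
                 avg_out = sp$avg_out, S = sp$S, O = O, weights = weights),
            class = "sse_attention")
}

#' @export
print.sse_attention <- function(x, ...) {
  d <- dim(x$O)
  cat(sprintf("<sse_attention> output %d x %d x %d x %d; channel gates in [%.3f, %.3f]; spatial gates in [%.3f, %.3f]\n",
              d[1], d[2], d[3], d[4], min(x$y), max(x$y), min(x$S), max(x$S)))
  invisible(x)
}
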