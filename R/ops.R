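# Functional forms of the network's computational primitives. Feature maps
# are arrays in (C, D, H, W) order; a plain 3D array is treated as a single
# channel. The layer stack in network.R reuses the same compiled kernels.

# coerce to the internal batched layout (C, D, H, W, N = 1)
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("a feature map must be a 3D (D,H,W) or 4D (C,D,H,W) array")
  if (length(d) == 3L) d <- c(1L, d)
  array(x, c(d, 1L))
}

drop_batch <- function(x) {
  d <- dim(x)
  array(x, d[1:4])
}

conv_out_len <- function(n, k, stride, dilation, pad)
  (n + 2L * pad - dilation * (k - 1L) - 1L) %/% stride + 1L

same_pad <- function(k, dilation) as.integer(dilation * (k - 1L) %/% 2L)

resolve_pad <- function(padding, k, dilation) {
  if (is.character(padding)) {
    padding <- match.arg(padding, c("same", "valid"))
    if (padding == "same") {
      if (k %% 2L == 0L) stop("'same' padding requires an odd kernel size")
      same_pad(k, dilation)
    } else 0L
  } else as.integer(padding)
}

#' Softmax of a numeric vector
#'
#' Numerically stable softmax; the result is positive and sums to 1.
#'
#' @param x numeric vector of real scores.
#' @return numeric vector of the same length.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Depthwise separable 3D convolution
#'
#' Applies a per-channel (depthwise) spatial convolution followed by a
#' 1 x 1 x 1 pointwise convolution that mixes channels. This factorization is
#' the parameter-saving workhorse of the lightweight architecture: a full
#' `k^3 * c_in * c_out` kernel is replaced by `k^3 * c_in + c_in * c_out`
#' weights.
#'
#' @param x feature map, a (C, D, H, W) array (3D input is taken as C = 1).
#' @param depthwise array of per-channel kernels, shape (k, k, k, C)
#'   (a single (k, k, k) kernel is accepted when C = 1).
#' @param pointwise mixing matrix of shape (C_out, C_in); a scalar is a
#'   1 x 1 matrix.
#' @param bias optional per-output-channel bias of length C_out.
#' @param stride positive integer spatial stride.
#' @param padding `"same"`, `"valid"`, or an explicit non-negative integer.
#' @param dilation dilation rate of the depthwise kernel.
#' @return A (C_out, D', H', W') array.
#' @export
depthwise_separable_conv3d <- function(x, depthwise, pointwise, bias = NULL,
                                       stride = 1L, padding = "same",
                                       dilation = 1L) {
  xb <- as_feature_map(x)
  C <- dim(xb)[1]
  if (length(dim(depthwise)) == 3L) {
    if (C != 1L) stop("depthwise kernel lacks the channel dimension")
    dim(depthwise) <- c(dim(depthwise), 1L)
  }
  kd <- dim(depthwise)
  if (kd[1] != kd[2] || kd[2] != kd[3])
    stop("depthwise kernels must be cubic (k x k x k)")
  if (kd[4] != C)
    stop(sprintf("channel mismatch: input has %d channels, depthwise kernels %d",
                 C, kd[4]))
  pointwise <- as.matrix(pointwise)
  if (ncol(pointwise) != C)
    stop(sprintf("channel mismatch: input has %d channels, pointwise expects %d",
                 C, ncol(pointwise)))
  pad <- resolve_pad(padding, kd[1], dilation)
  y <- dw_conv3d_fwd(xb, dim(xb), depthwise, kd[1],
                     as.integer(stride), as.integer(dilation), pad)
  yd <- dim(y)
  z <- pointwise %*% matrix(y, nrow = C)
  if (!is.null(bias)) {
    if (length(bias) != nrow(pointwise))
      stop("bias length must equal the number of output channels")
    z <- z + bias
  }
  array(z, c(nrow(pointwise), yd[2:4]))
}

#' Dilated 3D convolution with a single kernel
#'
#' Convolves each channel with the same cubic kernel whose taps are spaced by
#' the dilation rate `rate`; out-of-range taps contribute zero under zero
#' padding. With `rate = 1` this is a standard 3D convolution.
#'
#' @param x feature map, (C, D, H, W) or (D, H, W) array.
#' @param kernel cubic (k, k, k) weight array.
#' @param rate positive integer dilation rate.
#' @param padding `"same"`, `"valid"`, or an explicit integer.
#' @return Array with the same channel count as `x`.
#' @export
dilated_conv3d <- function(x, kernel, rate = 1L, padding = "same") {
  if (rate < 1L) stop("dilation `rate` must be >= 1")
  xb <- as_feature_map(x)
  C <- dim(xb)[1]
  k <- dim(kernel)
  if (length(k) != 3L || k[1] != k[2] || k[2] != k[3])
    stop("`kernel` must be a cubic (k, k, k) array")
  dw <- array(rep(kernel, C), c(k, C))
  pad <- resolve_pad(padding, k[1], rate)
  y <- dw_conv3d_fwd(xb, dim(xb), dw, k[1], 1L, as.integer(rate), pad)
  out <- drop_batch(y)
  if (length(dim(x)) == 3L) array(out, dim(out)[2:4]) else out
}

#' Parameter-free channel attention (normalization-and-shift variant)
#'
#' For every channel, the feature map is centered by its spatial mean,
#' scaled by `0.5 / (variance + lambda)` and shifted by 0.5; a sigmoid of
#' this normalized map is the attention mask, which multiplies the input
#' elementwise. The variance is the population (n-denominator) spatial
#' variance. A constant channel therefore gets the mask
#' `sigmoid(0.5) = 0.6224593`.
#'
#' @param x feature map, (C, D, H, W) or (D, H, W) array.
#' @param lambda small positive smoothing constant guarding zero variance.
#' @return Array of the same shape as `x`; the mask is attached as
#'   attribute `"mask"`.
#' @export
ils_attention <- function(x, lambda = 1e-4) {
  if (lambda <= 0) stop("`lambda` must be > 0")
  xb <- as_feature_map(x)
  res <- ils_forward(xb, lambda)
  out <- array(res$y, dim(x))
  attr(out, "mask") <- array(res$m, dim(x))
  out
}

# batched ILS forward shared with the layer stack: x is (C,D,H,W,N)
ils_forward <- function(x, lambda) {
  d <- dim(x)
  C <- d[1]; P <- prod(d[2:4]); N <- d[5]
  m3 <- array(x, c(C, P, N))
  mu <- cn_mean(m3)                                    # C x N
  v <- pmax(cn_mean(m3 * m3) - mu^2, 0)                # population variance
  a <- 0.5 / (v + lambda)                              # C x N
  bcast <- function(mat) aperm(array(mat, c(C, N, P)), c(1, 3, 2))
  xhat <- (m3 - bcast(mu)) * bcast(a) + 0.5
  m <- 1 / (1 + exp(-xhat))
  y <- m3 * m
  list(x = x, y = array(y, d), m = array(m, d), xhat = array(xhat, d),
       mu = mu, v = v, a = a)
}

#' Lightweight multi-scale fusion (functional form)
#'
#' Runs parallel depthwise-separable convolution branches at several kernel
#' scales with same padding, concatenates them, pools the concatenation with
#' 3D global average pooling to a descriptor `z`, maps `z` through a two-layer
#' gate `softmax(W2 ReLU(W1 z + b1) + b2)` to one fusion weight per scale, and
#' returns the convex combination of the branch outputs.
#'
#' @param x feature map, (C, D, H, W) array (3D input is taken as C = 1).
#' @param branch_params list with one element per scale, each a list with
#'   `depthwise` ((k, k, k, C) array) and `pointwise` ((C, C) matrix).
#' @param gate_params list with `W1` (hidden x S*C), `b1`, `W2` (S x hidden),
#'   `b2`.
#' @return The fused (C, D', H', W') array with attributes `"alpha"` (fusion
#'   weights, summing to 1) and `"z"` (the pooled descriptor).
#' @export
lmf_forward <- function(x, branch_params, gate_params) {
  xb <- as_feature_map(x)
  S <- length(branch_params)
  if (S < 2L) stop("the fusion block needs at least two scales")
  branches <- lapply(branch_params, function(p) {
    y <- depthwise_separable_conv3d(drop_batch(xb), p$depthwise, p$pointwise,
                                    stride = 1L, padding = "same")
    y
  })
  dims <- lapply(branches, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("branch outputs must be spatially aligned")
  z <- unlist(lapply(branches, mean_per_channel))
  h <- pmax(gate_params$W1 %*% z + gate_params$b1, 0)
  scores <- as.numeric(gate_params$W2 %*% h + gate_params$b2)
  alpha <- softmax(scores)
  out <- Reduce(`+`, Map(function(a, f) a * f, as.list(alpha), branches))
  attr(out, "alpha") <- alpha
  attr(out, "z") <- z
  out
}

# per-channel spatial mean of a (C, D, H, W) array
mean_per_channel <- function(f) {
  d <- dim(f)
  rowMeans(matrix(f, d[1], prod(d[2:4])))
}
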