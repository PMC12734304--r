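# Independent brute-force oracles used to validate the compiled convolution
# kernels, the parameter/FLOPs counters and the AUC statistic. These are
# deliberately naive (triple loops, closed formulas from configuration
# shapes, pair enumeration) and never share code with the implementation.

# direct full 3D convolution: x (C_in, D, H, W), kernel (k, k, k, C_in,
# C_out), zero padding, integer stride and dilation
oracle_conv3d <- function(x, kern, stride = 1L, pad = 0L, dilation = 1L) {
  dx <- dim(x)
  k <- dim(kern)[1]
  odim <- (dx[2:4] + 2L * pad - dilation * (k - 1L) - 1L) %/% stride + 1L
  cout <- dim(kern)[5]
  y <- array(0, c(cout, odim))
  for (co in seq_len(cout))
    for (od in seq_len(odim[1])) for (oh in seq_len(odim[2]))
      for (ow in seq_len(odim[3])) {
        acc <- 0
        for (ci in seq_len(dx[1]))
          for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
            id <- (od - 1L) * stride - pad + dilation * (i - 1L) + 1L
            ih <- (oh - 1L) * stride - pad + dilation * (j - 1L) + 1L
            iw <- (ow - 1L) * stride - pad + dilation * (l - 1L) + 1L
            if (id >= 1 && id <= dx[2] && ih >= 1 && ih <= dx[3] &&
                iw >= 1 && iw <= dx[4])
              acc <- acc + x[ci, id, ih, iw] * kern[i, j, l, ci, co]
          }
        y[co, od, oh, ow] <- acc
      }
  y
}

# depthwise oracle as a block-diagonal full convolution
oracle_depthwise <- function(x, w, stride = 1L, pad = 0L, dilation = 1L) {
  C <- dim(x)[1]
  k <- dim(w)[1]
  kern <- array(0, c(k, k, k, C, C))
  for (c in seq_len(C)) kern[, , , c, c] <- w[, , , c]
  oracle_conv3d(x, kern, stride, pad, dilation)
}

# expected trainable-parameter count enumerated from a network configuration
# using the closed formulas (kernel volume x c_in x c_out + per-channel
# norm/bias terms), independent of the model object
oracle_params_from_config <- function(cfg) {
  K <- length(cfg$stage_widths)
  total <- cfg$stem_channels * 1 + 2 * cfg$stem_channels   # stem conv + bn
  cur <- cfg$stem_channels
  for (s in seq_len(K)) {
    w <- cfg$stage_widths[s]
    total <- total + 27 * cur + cur * w + 2 * w            # dw + pw + bn
    cur <- w
    if (s == cfg$lmf_position) {
      S <- length(cfg$lmf_scales)
      for (k in cfg$lmf_scales)
        total <- total + k^3 * cur + cur * cur + 2 * cur   # branch dw+pw+bn
      gh <- max(4, (S * cur) %/% 4)
      total <- total + gh * S * cur + gh + S * gh + S      # gate mlp
    }
  }
  total + cfg$num_classes * cur + cfg$num_classes          # head
}

# expected FLOPs walked from the configuration with the printed conv formula
oracle_flops_from_config <- function(cfg, input_shape) {
  K <- length(cfg$stage_widths)
  dims <- input_shape[2:4]
  flops <- 2 * prod(dims) * 1 * cfg$stem_channels
  cur <- cfg$stem_channels
  dil <- rep(1L, K)
  nd <- min(2L, K)
  dil[(K - nd + 1L):K] <- cfg$dilation_rates[seq_len(nd)]
  for (s in seq_len(K)) {
    w <- cfg$stage_widths[s]
    pad <- dil[s]
    dims <- (dims + 2 * pad - dil[s] * 2 - 1) %/% cfg$stage_strides[s] + 1
    flops <- flops + 2 * prod(dims) * 27 * cur        # depthwise
    flops <- flops + 2 * prod(dims) * cur * w         # pointwise
    cur <- w
    if (s == cfg$lmf_position)
      for (k in cfg$lmf_scales)
        flops <- flops + 2 * prod(dims) * k^3 * cur + 2 * prod(dims) * cur * cur
  }
  flops + 2 * cur * cfg$num_classes
}

# AUC by explicit enumeration of all (positive, negative) pairs
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# small random architecture generator for property tests
random_tiny_config <- function(seed) {
  set.seed(seed)
  K <- sample(2:3, 1)
  base <- sample(2:5, 1)
  widths <- cumsum(c(base, sample(0:3, K - 1, replace = TRUE)))
  network_config(stage_widths = widths,
                 stem_channels = sample(2:4, 1),
                 stage_strides = sample(1:2, K, replace = TRUE),
                 lmf_position = sample(K, 1),
                 ils_positions = sample(K, 1),
                 dilation_rates = sample(1:2, 2, replace = TRUE),
                 input_shape = c(1, 7, 9, 9))
}

rand_input <- function(shape, n = 2L, seed = 1L) {
  set.seed(seed)
  array(runif(prod(shape[2:4]) * n), c(1, shape[2:4], n))
}

# reduced phantom generation spec used by the end-to-end experiments: the
# axial extent is scaled down from 73 to 32 slices, and the signal slab is
# placed at the same relative depth
smoke_phantom_spec <- function(effect_size = 0.4, seed = 1L)
  phantom_spec(shape = c(32, 48, 48), effect_size = effect_size,
               signal_slab = c(9, 18), seed = seed)

# parameter sets for the functional multi-scale fusion block
make_lmf_params <- function(C, scales = c(3, 5), seed = 1, identity = FALSE) {
  set.seed(seed)
  branch <- lapply(scales, function(k) {
    dw <- if (identity) {
      d <- array(0, c(k, k, k, C))
      d[(k + 1) / 2, (k + 1) / 2, (k + 1) / 2, ] <- 1
      d
    } else array(rnorm(k^3 * C, 0, 0.3), c(k, k, k, C))
    pw <- if (identity) diag(C) else matrix(rnorm(C * C, 0, 0.3), C, C)
    list(depthwise = dw, pointwise = pw)
  })
  S <- length(scales)
  gh <- max(4, S * C %/% 4)
  gate <- list(W1 = matrix(rnorm(gh * S * C, 0, 0.3), gh, S * C),
               b1 = rnorm(gh, 0, 0.1),
               W2 = matrix(rnorm(S * gh, 0, 0.3), S, gh),
               b2 = rnorm(S, 0, 0.1))
  list(branch = branch, gate = gate)
}
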