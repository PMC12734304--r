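# Internal layer engine. A model is an ordered list of layers; each layer is
# a list with a `type`, learnable `params`, optional `buffers` (batch-norm
# running statistics) and structural attributes. Batched activations are
# arrays in (C, D, H, W, N) order until global average pooling, after which
# they are (C, N) matrices. Every layer type has a forward returning
# (out, cache, layer) and a backward returning (gin, grads); the analytic
# backward passes are validated against finite differences in the test suite.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# ---- elementary forwards/backwards ----------------------------------------

fwd_pointwise <- function(layer, x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], length(x) / d[1])
  y <- layer$params$W %*% xm
  if (!is.null(layer$params$b)) y <- y + layer$params$b
  dim(y) <- c(nrow(layer$params$W), d[2:5])
  list(out = y, cache = list(x = x))
}

bwd_pointwise <- function(layer, cache, g) {
  d <- dim(cache$x)
  co <- nrow(layer$params$W)
  gm <- g
  dim(gm) <- c(co, length(g) / co)
  xm <- cache$x
  dim(xm) <- c(d[1], length(xm) / d[1])
  grads <- list(W = tcrossprod(gm, xm))
  if (!is.null(layer$params$b)) grads$b <- .rowSums(gm, co, ncol(gm))
  gin <- crossprod(layer$params$W, gm)
  dim(gin) <- d
  list(gin = gin, grads = grads)
}

fwd_depthwise <- function(layer, x) {
  k <- dim(layer$params$W)[1]
  y <- dw_conv3d_fwd(x, dim(x), layer$params$W, k,
                     layer$stride, layer$dilation, layer$pad)
  list(out = y, cache = list(x = x, ydim = dim(y)))
}

bwd_depthwise <- function(layer, cache, g) {
  k <- dim(layer$params$W)[1]
  gw <- dw_conv3d_bwd_weight(cache$x, dim(cache$x), g, cache$ydim,
                             k, layer$stride, layer$dilation, layer$pad)
  gx <- dw_conv3d_bwd_input(g, cache$ydim, layer$params$W, k,
                            layer$stride, layer$dilation, layer$pad,
                            dim(cache$x))
  list(gin = gx, grads = list(W = gw))
}

fwd_batchnorm <- function(layer, x, training) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], length(x) / d[1])
  if (training) {
    M <- ncol(xm)
    mu <- .rowMeans(xm, d[1], M)
    v <- .rowMeans(xm * xm, d[1], M) - mu^2
    v <- pmax(v, 0)
    layer$buffers$running_mean <-
      (1 - BN_MOMENTUM) * layer$buffers$running_mean + BN_MOMENTUM * mu
    layer$buffers$running_var <-
      (1 - BN_MOMENTUM) * layer$buffers$running_var + BN_MOMENTUM * v
  } else {
    mu <- layer$buffers$running_mean
    v <- layer$buffers$running_var
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - mu) * ivar
  y <- layer$params$gamma * xhat + layer$params$beta
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, ivar = ivar, d = d,
                             training = training),
       layer = layer)
}

bwd_batchnorm <- function(layer, cache, g) {
  d <- cache$d
  gm <- g
  M <- length(g) / d[1]
  dim(gm) <- c(d[1], M)
  gxh <- gm * cache$xhat
  ggamma <- .rowSums(gxh, d[1], M)
  gbeta <- .rowSums(gm, d[1], M)
  gxhat <- gm * layer$params$gamma
  if (cache$training) {
    gx <- cache$ivar * (gxhat - ggamma * layer$params$gamma *
                          cache$xhat / M - gbeta * layer$params$gamma / M)
  } else {
    gx <- cache$ivar * gxhat
  }
  dim(gx) <- d
  list(gin = gx, grads = list(gamma = ggamma, beta = gbeta))
}

fwd_relu <- function(layer, x) {
  pos <- x > 0
  list(out = x * pos, cache = list(pos = pos))
}

bwd_relu <- function(layer, cache, g) {
  list(gin = g * cache$pos, grads = list())
}

fwd_ils <- function(layer, x) {
  res <- ils_forward(x, layer$lambda)
  list(out = res$y, cache = res)
}

bwd_ils <- function(layer, cache, g) {
  d <- dim(g)
  C <- d[1]; P <- prod(d[2:4]); N <- d[5]
  g3 <- array(g, c(C, P, N))
  x3 <- array(cache$x, c(C, P, N))
  m3 <- array(cache$m, c(C, P, N))
  xh3 <- array(cache$xhat, c(C, P, N))
  sig_d <- m3 * (1 - m3)
  t3 <- g3 * x3 * sig_d                     # dL/dXhat contributions
  bcast <- function(mat) aperm(array(mat, c(C, N, P)), c(1, 3, 2))
  mu_b <- bcast(cache$mu)
  a_b <- bcast(cache$a)
  Tsum <- bcast(cn_sum(t3))                 # sum_q t_q
  St <- bcast(cn_sum(t3 * (x3 - mu_b)))     # sum_q t_q (x_q - mu)
  denom_b <- bcast((cache$v + layer$lambda)^2)
  gx <- g3 * m3 + a_b * t3 - a_b * Tsum / P -
    St * (x3 - mu_b) / (P * denom_b)
  list(gin = array(gx, d), grads = list())
}

# sum over the middle (spatial) index of a (C, P, N) array -> C x N
cn_sum <- function(a3) {
  d <- dim(a3)
  matrix(colSums(matrix(aperm(a3, c(2, 1, 3)), d[2])), d[1])
}

cn_mean <- function(a3) cn_sum(a3) / dim(a3)[2]

fwd_gap <- function(layer, x) {
  d <- dim(x)
  m3 <- array(x, c(d[1], prod(d[2:4]), d[5]))
  list(out = cn_mean(m3), cache = list(d = d))
}

bwd_gap <- function(layer, cache, g) {
  d <- cache$d
  P <- prod(d[2:4])
  gin <- aperm(array(g / P, c(d[1], d[5], P)), c(1, 3, 2))
  list(gin = array(gin, d), grads = list())
}

fwd_dense <- function(layer, x) {
  y <- layer$params$W %*% x + layer$params$b
  list(out = y, cache = list(x = x))
}

bwd_dense <- function(layer, cache, g) {
  list(gin = t(layer$params$W) %*% g,
       grads = list(W = g %*% t(cache$x), b = rowSums(g)))
}

# ---- multi-scale fusion block ---------------------------------------------

# Branch i: depthwise (k_i) -> pointwise -> batch norm -> ReLU. The gate pools
# the channel-concatenation of the branch outputs and produces one softmax
# weight per scale; the output is the convex combination of the branches.
fwd_lmf <- function(layer, x, training) {
  S <- length(layer$scales)
  d <- dim(x)
  branches <- vector("list", S)
  for (i in seq_len(S)) {
    k <- layer$scales[i]
    dwk <- layer$params[[paste0("dw", i)]]
    y <- dw_conv3d_fwd(x, d, dwk, k, 1L, 1L, same_pad(k, 1L))
    pw <- layer$params[[paste0("pw", i)]]
    p <- array(pw %*% matrix(y, nrow = d[1]), c(nrow(pw), dim(y)[2:5]))
    bn_layer <- list(params = list(gamma = layer$params[[paste0("gam", i)]],
                                   beta = layer$params[[paste0("bet", i)]]),
                     buffers = list(running_mean = layer$buffers[[paste0("rm", i)]],
                                    running_var = layer$buffers[[paste0("rv", i)]]))
    bn <- fwd_batchnorm(bn_layer, p, training)
    layer$buffers[[paste0("rm", i)]] <- bn$layer$buffers$running_mean
    layer$buffers[[paste0("rv", i)]] <- bn$layer$buffers$running_var
    r <- pmax(bn$out, 0)
    branches[[i]] <- list(y = y, p = p, bn_cache = bn$cache, bn_out = bn$out,
                          r = r)
  }
  C <- dim(branches[[1]]$r)[1]
  N <- d[5]
  P <- prod(dim(branches[[1]]$r)[2:4])
  z <- do.call(rbind, lapply(branches, function(b)
    cn_mean(array(b$r, c(C, P, N)))))                  # (S*C) x N
  hpre <- layer$params$W1 %*% z + layer$params$b1
  h <- pmax(hpre, 0)
  scores <- layer$params$W2 %*% h + layer$params$b2    # S x N
  emax <- apply(scores, 2, max)
  e <- exp(sweep(scores, 2, emax))
  alpha <- sweep(e, 2, colSums(e), `/`)                # S x N
  out <- 0
  for (i in seq_len(S))
    out <- out + sweep_batch(branches[[i]]$r, alpha[i, ])
  cache <- list(x = x, branches = branches, z = z, hpre = hpre, h = h,
                alpha = alpha, C = C, P = P, N = N, d = d)
  list(out = out, cache = cache, layer = layer)
}

# multiply a (C,D,H,W,N) array by a per-sample scalar vector of length N
sweep_batch <- function(a, s) {
  d <- dim(a)
  array(matrix(a, ncol = d[5]) %*% diag(s, d[5]), d)
}

bwd_lmf <- function(layer, cache, g) {
  S <- length(layer$scales)
  C <- cache$C; P <- cache$P; N <- cache$N
  grads <- list()
  br <- cache$branches
  galpha <- matrix(0, S, N)
  for (i in seq_len(S))
    galpha[i, ] <- colSums(matrix(g * br[[i]]$r, ncol = N))
  # softmax backward (per column)
  a <- cache$alpha
  gs <- a * sweep(galpha, 2, colSums(a * galpha))
  # gate MLP backward
  grads$W2 <- gs %*% t(cache$h)
  grads$b2 <- rowSums(gs)
  gh <- t(layer$params$W2) %*% gs
  gh[cache$hpre <= 0] <- 0
  grads$W1 <- gh %*% t(cache$z)
  grads$b1 <- rowSums(gh)
  gz <- t(layer$params$W1) %*% gh                      # (S*C) x N
  gx <- 0
  for (i in seq_len(S)) {
    gr <- sweep_batch(g, a[i, ])
    # pooled-descriptor path: channel block i of gz spread over positions
    gz_i <- gz[((i - 1) * C + 1):(i * C), , drop = FALSE] / P
    gr <- gr + array(aperm(array(gz_i, c(C, N, P)), c(1, 3, 2)),
                     dim(gr))
    gr[br[[i]]$bn_out <= 0] <- 0
    bn_layer <- list(params = list(gamma = layer$params[[paste0("gam", i)]],
                                   beta = layer$params[[paste0("bet", i)]]))
    bn <- bwd_batchnorm(bn_layer, br[[i]]$bn_cache, gr)
    grads[[paste0("gam", i)]] <- bn$grads$gamma
    grads[[paste0("bet", i)]] <- bn$grads$beta
    pw <- layer$params[[paste0("pw", i)]]
    gpm <- matrix(bn$gin, nrow = nrow(pw))
    ym <- matrix(br[[i]]$y, nrow = ncol(pw))
    grads[[paste0("pw", i)]] <- gpm %*% t(ym)
    gy <- array(t(pw) %*% gpm, dim(br[[i]]$y))
    k <- layer$scales[i]
    dwk <- layer$params[[paste0("dw", i)]]
    grads[[paste0("dw", i)]] <-
      dw_conv3d_bwd_weight(cache$x, cache$d, gy, dim(gy), k, 1L, 1L,
                           same_pad(k, 1L))
    gx <- gx + dw_conv3d_bwd_input(gy, dim(gy), dwk, k, 1L, 1L,
                                   same_pad(k, 1L), cache$d)
  }
  list(gin = gx, grads = grads)
}

# ---- dispatch --------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    pointwise = fwd_pointwise(layer, x),
    depthwise = fwd_depthwise(layer, x),
    batchnorm = fwd_batchnorm(layer, x, training),
    relu = fwd_relu(layer, x),
    ils = fwd_ils(layer, x),
    gap = fwd_gap(layer, x),
    dense = fwd_dense(layer, x),
    lmf = fwd_lmf(layer, x, training),
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, g) {
  switch(layer$type,
    pointwise = bwd_pointwise(layer, cache, g),
    depthwise = bwd_depthwise(layer, cache, g),
    batchnorm = bwd_batchnorm(layer, cache, g),
    relu = bwd_relu(layer, cache, g),
    ils = bwd_ils(layer, cache, g),
    gap = bwd_gap(layer, cache, g),
    dense = bwd_dense(layer, cache, g),
    lmf = bwd_lmf(layer, cache, g),
    stop("unknown layer type: ", layer$type))
}

# Full forward pass. Returns scores (num_classes x N), the per-layer caches
# (when keep_cache) and the possibly updated model (running statistics).
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    lr <- layer_forward(model$layers[[i]], x, training)
    x <- lr$out
    if (!is.null(lr$layer)) model$layers[[i]] <- lr$layer
    if (keep_cache) caches[[i]] <- lr$cache
  }
  list(scores = x, caches = caches, model = model)
}

# Backward pass from the score gradient; returns grads named by layer.
model_backward <- function(model, caches, gscores) {
  grads <- vector("list", length(model$layers))
  names(grads) <- names(model$layers)
  g <- gscores
  for (i in rev(seq_along(model$layers))) {
    lb <- layer_backward(model$layers[[i]], caches[[i]], g)
    grads[[i]] <- lb$grads
    g <- lb$gin
  }
  grads
}
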