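test_that("depthwise separable conv matches hand-computed cases", {
  x <- array(1, c(3, 3, 3))
  y <- depthwise_separable_conv3d(x, array(1, c(3, 3, 3)), 1,
                                  padding = "valid")
  expect_equal(dim(y), c(1, 1, 1, 1))
  expect_equal(as.numeric(y), 27)

  # centered-delta depthwise + identity pointwise is the identity map
  set.seed(1)
  xr <- array(rnorm(2 * 4 * 5 * 5), c(2, 4, 5, 5))
  delta <- array(0, c(3, 3, 3, 2)); delta[2, 2, 2, ] <- 1
  expect_equal(depthwise_separable_conv3d(xr, delta, diag(2),
                                          padding = "same"),
               xr)

  # zero pointwise annihilates, bias survives
  dw <- array(rnorm(27 * 2), c(3, 3, 3, 2))
  out <- depthwise_separable_conv3d(xr, dw, matrix(0, 3, 2),
                                    bias = c(1, 2, 3), padding = "same")
  expect_equal(unique(as.numeric(out[1, , , ])), 1)
  expect_equal(unique(as.numeric(out[3, , , ])), 3)

  expect_error(depthwise_separable_conv3d(xr, array(1, c(3, 3, 3, 5)),
                                          diag(5)),
               "channel mismatch")
})

test_that("depthwise separable conv equals the composed full convolution", {
  for (seed in 1:5) {
    set.seed(seed)
    stride <- sample(1:2, 1)
    dilation <- sample(1:2, 1)
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    x <- array(rnorm(cin * 6 * 7 * 7), c(cin, 6, 7, 7))
    dw <- array(rnorm(27 * cin), c(3, 3, 3, cin))
    pw <- matrix(rnorm(cout * cin), cout, cin)
    got <- depthwise_separable_conv3d(x, dw, pw, stride = stride,
                                      padding = 0L, dilation = dilation)
    # rank-structured full kernel: kern[,,,ci,co] = dw[,,,ci] * pw[co,ci]
    kern <- array(0, c(3, 3, 3, cin, cout))
    for (ci in seq_len(cin)) for (co in seq_len(cout))
      kern[, , , ci, co] <- dw[, , , ci] * pw[co, ci]
    expect_equal(got, oracle_conv3d(x, kern, stride, 0L, dilation),
                 tolerance = 1e-12)
  }
})

test_that("dilated convolution reduces to standard convolution at rate 1", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 6), c(1, 6, 6, 6))
  kern <- array(rnorm(27), c(3, 3, 3))
  got <- dilated_conv3d(x, kern, rate = 1, padding = "valid")
  expect_equal(got, oracle_conv3d(x, array(kern, c(3, 3, 3, 1, 1)),
                                  1L, 0L, 1L),
               tolerance = 1e-12)
})

test_that("dilated taps land on the dilated lattice only", {
  kern <- array(1, c(3, 3, 3))
  on_lattice <- c(-2, 0, 2)
  offsets <- list(c(0, 0, 0), c(2, 0, -2), c(-2, -2, -2),   # on the lattice
                  c(1, 0, 0), c(2, 1, 0), c(-1, 2, 2))      # off the lattice
  for (off in offsets) {
    x <- array(0, c(5, 5, 5))
    x[3 + off[1], 3 + off[2], 3 + off[3]] <- 1
    y <- dilated_conv3d(x, kern, rate = 2, padding = "same")
    expect_equal(y[3, 3, 3] != 0, all(off %in% on_lattice),
                 info = paste(off, collapse = ","))
  }
  # unit kernel is the identity at any rate
  set.seed(4)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  expect_equal(dilated_conv3d(x, array(1, c(1, 1, 1)), rate = 3), x)
  expect_error(dilated_conv3d(x, array(1, c(1, 1, 1)), rate = 0), ">= 1")
})

test_that("attention mask follows the normalization-and-shift formula", {
  # constant channel: normalized map is 0.5 everywhere
  xc <- array(2, c(1, 2, 2, 1))
  out <- ils_attention(xc)
  expect_equal(unique(as.numeric(attr(out, "mask"))),
               1 / (1 + exp(-0.5)))
  expect_equal(as.numeric(out), rep(2 * 0.6224593, 4), tolerance = 1e-6)

  # two-voxel channel {0, 1}: hand evaluation with population variance
  x2 <- array(c(0, 1), c(1, 2, 1, 1))
  out2 <- ils_attention(x2, lambda = 1e-4)
  m <- attr(out2, "mask")
  expect_equal(m[1, 2, 1, 1], 0.81756, tolerance = 1e-4)
  expect_equal(out2[1, 2, 1, 1], 0.81756, tolerance = 1e-4)
  expect_equal(out2[1, 1, 1, 1], 0)

  # the sigmoid mask is strictly inside (0, 1) and preserves sign
  set.seed(5)
  xr <- array(rnorm(3 * 4 * 4 * 4), c(3, 4, 4, 4))
  outr <- ils_attention(xr)
  mr <- attr(outr, "mask")
  expect_true(all(mr > 0 & mr < 1))
  expect_true(all(sign(outr) == sign(xr)))
  expect_equal(dim(outr), dim(xr))
  expect_error(ils_attention(xr, lambda = 0), "> 0")
})

test_that("fusion pools the branch concatenation to one value per channel", {
  # identity branches on a single-channel 4x3x3 map: the pooled descriptor
  # has length 2 (scales x channels) and each entry is the 36-position mean
  x <- array(seq_len(36) / 36, c(1, 4, 3, 3))
  p <- make_lmf_params(1, identity = TRUE)
  out <- lmf_forward(x, p$branch, p$gate)
  z <- attr(out, "z")
  expect_length(z, 2)
  expect_equal(as.numeric(z), rep(mean(x), 2))
})

test_that("softmax matches the worked example and fusion weights are convex", {
  expect_equal(round(softmax(c(2.0, 1.0, 0.1)), 2), c(0.66, 0.24, 0.10))
  for (seed in 1:5) {
    set.seed(seed)
    x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
    p <- make_lmf_params(2, seed = seed)
    out <- lmf_forward(x, p$branch, p$gate)
    a <- attr(out, "alpha")
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a > 0))
  }
})

test_that("identical branches make the fusion output independent of the gate", {
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  p <- make_lmf_params(2, scales = c(3, 3), seed = 8)
  p$branch[[2]] <- p$branch[[1]]
  out <- lmf_forward(x, p$branch, p$gate)
  direct <- depthwise_separable_conv3d(x, p$branch[[1]]$depthwise,
                                       p$branch[[1]]$pointwise,
                                       padding = "same")
  expect_equal(array(out, dim(direct)), direct, tolerance = 1e-12)
})
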