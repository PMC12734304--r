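# Network configuration and instantiation. The reference architecture is:
# 1x1x1 stem convolution (channel mapping) -> depthwise-separable stages with
# batch norm + ReLU (stride-2 stages downsample; the last two stages use
# dilated depthwise kernels at stride 1) -> multi-scale fusion block at one
# stage -> parameter-free attention at configurable stages -> global average
# pooling -> fully connected head.

# width multiplier for the full-size configuration, chosen by
# calibrate_width_multiplier() so the unpruned model lands on the published
# 0.92 M parameter budget
WIDTH_MULTIPLIER_DEFAULT <- 1.95

#' Network architecture configuration
#'
#' @param stage_widths integer vector of per-stage output channel counts;
#'   must be positive and non-decreasing.
#' @param stem_channels channels produced by the 1x1x1 stem convolution.
#' @param stage_strides per-stage spatial stride (default: 2 for all but the
#'   final two stages, which run at stride 1 with dilation).
#' @param lmf_position index of the stage after which the multi-scale fusion
#'   block is inserted.
#' @param lmf_scales odd kernel sizes of the fusion branches.
#' @param ils_positions stage indices after which the attention module is
#'   applied.
#' @param dilation_rates dilation rates of the last two stages.
#' @param num_classes number of output classes.
#' @param input_shape expected input, (channels, depth, height, width).
#' @param ils_lambda smoothing constant of the attention module.
#' @return An object of class `slim3d_network_config`.
#' @export
network_config <- function(stage_widths = c(24, 64, 128, 256, 512),
                           stem_channels = 24,
                           stage_strides = NULL,
                           lmf_position = max(1L, length(stage_widths) - 2L),
                           lmf_scales = c(3, 5),
                           ils_positions = length(stage_widths),
                           dilation_rates = c(2, 4),
                           num_classes = 2,
                           input_shape = c(1, 73, 96, 96),
                           ils_lambda = 1e-4) {
  stage_widths <- as.integer(stage_widths)
  K <- length(stage_widths)
  problems <- character(0)
  if (K < 1L || any(stage_widths < 1L))
    problems <- c(problems, "stage_widths must be positive")
  if (is.unsorted(stage_widths))
    problems <- c(problems, "stage_widths must be non-decreasing")
  if (is.null(stage_strides))
    stage_strides <- c(rep(2L, max(0L, K - 2L)), rep(1L, min(2L, K)))
  stage_strides <- as.integer(stage_strides)
  if (length(stage_strides) != K)
    problems <- c(problems, "stage_strides must match stage_widths in length")
  if (lmf_position < 1L || lmf_position > K)
    problems <- c(problems, "lmf_position out of range")
  if (length(ils_positions) && (min(ils_positions) < 1L || max(ils_positions) > K))
    problems <- c(problems, "ils_positions out of range")
  if (any(lmf_scales %% 2 == 0))
    problems <- c(problems, "lmf_scales must be odd")
  if (length(lmf_scales) < 2L)
    problems <- c(problems, "at least two fusion scales are required")
  if (num_classes < 2L)
    problems <- c(problems, "num_classes must be >= 2")
  if (length(input_shape) != 4L || input_shape[1] != 1L)
    problems <- c(problems, "input_shape must be (1, D, H, W)")
  n_dil <- min(2L, K)
  dilation_rates <- as.integer(dilation_rates)[seq_len(n_dil)]
  if (any(is.na(dilation_rates)) || any(dilation_rates < 1L))
    problems <- c(problems, "dilation_rates must be >= 1")
  if (length(problems))
    stop("invalid network config: ", paste(problems, collapse = "; "))
  structure(list(stage_widths = stage_widths,
                 stem_channels = as.integer(stem_channels),
                 stage_strides = stage_strides,
                 lmf_position = as.integer(lmf_position),
                 lmf_scales = as.integer(lmf_scales),
                 ils_positions = as.integer(ils_positions),
                 dilation_rates = dilation_rates,
                 num_classes = as.integer(num_classes),
                 input_shape = as.integer(input_shape),
                 ils_lambda = ils_lambda),
            class = "slim3d_network_config")
}

#' Full-size default configuration
#'
#' The reference five-stage architecture with a 24-channel stem. Stage widths
#' are the base ladder (24, 64, 128, 256, 512) scaled by a width multiplier;
#' the default multiplier was fixed once with [calibrate_width_multiplier()]
#' so that the unpruned parameter count matches the published 0.92 M budget.
#'
#' @param width_multiplier multiplicative factor on the stage widths.
#' @param input_shape input geometry, (1, depth, height, width).
#' @return A [network_config()].
#' @export
default_network_config <- function(width_multiplier = WIDTH_MULTIPLIER_DEFAULT,
                                   input_shape = c(1, 73, 96, 96)) {
  network_config(stage_widths = round(width_multiplier * c(24, 64, 128, 256, 512)),
                 stem_channels = 24,
                 lmf_position = 3,
                 ils_positions = 5,
                 input_shape = input_shape)
}

#' Reduced configuration for desk-scale experiments
#'
#' A three-stage network (all widths at or below 32) for smoke tests and the
#' synthetic-cohort experiments, with the fusion block at the middle stage,
#' attention before the head, and dilation on the last two stages.
#'
#' @param input_shape input geometry, (1, depth, height, width).
#' @return A [network_config()].
#' @export
tiny_network_config <- function(input_shape = c(1, 32, 48, 48)) {
  network_config(stage_widths = c(8, 16, 32), stem_channels = 8,
                 stage_strides = c(2, 2, 2), lmf_position = 2,
                 ils_positions = 3, dilation_rates = c(2, 4),
                 input_shape = input_shape)
}

he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

#' Instantiate a model from a configuration
#'
#' Builds the layer stack and initializes all weights reproducibly from the
#' seed (He-style normal initialization for convolution and linear weights,
#' unit scale / zero shift for batch normalization).
#'
#' @param cfg a [network_config()].
#' @param seed integer seed controlling the initialization.
#' @return An object of class `slim3d_model`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "slim3d_network_config"))
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(derive_seed(seed, 0L))
  layers <- list()
  add <- function(name, layer) {
    layer$name <- name
    layers[[name]] <<- layer
  }
  new_bn <- function(C, prunable) {
    list(type = "batchnorm",
         params = list(gamma = rep(1, C), beta = rep(0, C)),
         buffers = list(running_mean = rep(0, C), running_var = rep(1, C)),
         prunable = prunable, mask = rep(TRUE, C))
  }
  add("stem.conv", list(type = "pointwise",
                        params = list(W = matrix(he_init(cfg$stem_channels, 1),
                                                 cfg$stem_channels, 1))))
  add("stem.bn", new_bn(cfg$stem_channels, FALSE))
  add("stem.relu", list(type = "relu"))
  cur <- cfg$stem_channels
  K <- length(cfg$stage_widths)
  dil <- rep(1L, K)
  nd <- length(cfg$dilation_rates)
  if (nd > 0) dil[(K - nd + 1L):K] <- cfg$dilation_rates
  for (s in seq_len(K)) {
    w <- cfg$stage_widths[s]
    pre <- sprintf("stage%d", s)
    add(paste0(pre, ".dw"),
        list(type = "depthwise",
             params = list(W = array(he_init(27 * cur, 27), c(3, 3, 3, cur))),
             stride = cfg$stage_strides[s], dilation = dil[s],
             pad = same_pad(3L, dil[s])))
    add(paste0(pre, ".pw"),
        list(type = "pointwise",
             params = list(W = matrix(he_init(w * cur, cur), w, cur))))
    add(paste0(pre, ".bn"), new_bn(w, TRUE))
    add(paste0(pre, ".relu"), list(type = "relu"))
    cur <- w
    if (s == cfg$lmf_position) {
      S <- length(cfg$lmf_scales)
      params <- list()
      buffers <- list()
      for (i in seq_len(S)) {
        k <- cfg$lmf_scales[i]
        params[[paste0("dw", i)]] <- array(he_init(k^3 * cur, k^3),
                                           c(k, k, k, cur))
        params[[paste0("pw", i)]] <- matrix(he_init(cur * cur, cur), cur, cur)
        params[[paste0("gam", i)]] <- rep(1, cur)
        params[[paste0("bet", i)]] <- rep(0, cur)
        buffers[[paste0("rm", i)]] <- rep(0, cur)
        buffers[[paste0("rv", i)]] <- rep(1, cur)
      }
      gh <- max(4L, (S * cur) %/% 4L)
      params$W1 <- matrix(he_init(gh * S * cur, S * cur), gh, S * cur)
      params$b1 <- rep(0, gh)
      params$W2 <- matrix(he_init(S * gh, gh), S, gh)
      params$b2 <- rep(0, S)
      add("lmf", list(type = "lmf", params = params, buffers = buffers,
                      scales = cfg$lmf_scales, channels = cur))
    }
    if (s %in% cfg$ils_positions)
      add(sprintf("ils%d", s), list(type = "ils", lambda = cfg$ils_lambda))
  }
  add("head.gap", list(type = "gap"))
  add("head.fc", list(type = "dense",
                      params = list(W = matrix(he_init(cfg$num_classes * cur,
                                                       cur),
                                               cfg$num_classes, cur),
                                    b = rep(0, cfg$num_classes))))
  model <- structure(list(config = cfg, layers = layers,
                          prune = new_prune_state(layers)),
                     class = "slim3d_model")
  model
}

#' @export
print.slim3d_model <- function(x, ...) {
  rep <- complexity_report(x)
  cat(sprintf("<slim3d_model  %d layers  %s parameters  input (%s)>\n",
              length(x$layers), format(rep$para, big.mark = ","),
              paste(x$config$input_shape, collapse = ", ")))
  invisible(x)
}

# stack a list of (D,H,W) arrays (or volumes) into a (1,D,H,W,N) batch
volumes_to_batch <- function(vols) {
  arrs <- lapply(vols, function(v) if (inherits(v, "slim3d_volume")) v$data else v)
  d <- dim(arrs[[1]])
  array(unlist(arrs, use.names = FALSE), c(1L, d, length(arrs)))
}

#' Predict the class of one or more volumes
#'
#' Runs the network in evaluation mode (batch-norm running statistics) and
#' applies a softmax to the scores. Ties are broken toward the lower class
#' index.
#'
#' @param object a `slim3d_model`.
#' @param newdata a [volume()], a 3D array, or a list of either.
#' @param ... unused.
#' @return A list with `class` (integer vector, 0-based) and `prob`
#'   (N x num_classes matrix of class probabilities).
#' @export
predict.slim3d_model <- function(object, newdata, ...) {
  vols <- if (inherits(newdata, "slim3d_volume") || is.array(newdata))
    list(newdata) else newdata
  x <- volumes_to_batch(vols)
  exp_shape <- object$config$input_shape
  if (!all(dim(x)[1:4] == exp_shape))
    stop(sprintf("input shape (%s) does not match the model's expected (%s)",
                 paste(dim(x)[1:4], collapse = ", "),
                 paste(exp_shape, collapse = ", ")))
  scores <- model_forward(object, x, training = FALSE)$scores
  probs <- apply(scores, 2, softmax)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = object$config$num_classes)
  cls <- apply(probs, 2, which.max) - 1L
  list(class = as.integer(cls), prob = t(probs))
}

# accuracy and scores of a model over a list of volumes; batched for memory
model_evaluate <- function(model, vols, labels, batch_size = 8L) {
  n <- length(vols)
  pred <- integer(n)
  prob1 <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    p <- predict(model, vols[i:j])
    pred[i:j] <- p$class
    prob1[i:j] <- p$prob[, 2L]
    i <- j + 1L
  }
  list(accuracy = mean(pred == labels), pred = pred, prob1 = prob1)
}
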