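# Model complexity profiler: parameter count, FLOPs at a stated input shape,
# model size, and performance density (accuracy per million parameters).

#' Count trainable parameters
#'
#' Direct enumeration of every trainable entry: convolution kernels,
#' pointwise/linear weight matrices, biases, and batch-normalization
#' scale/shift pairs. Running statistics are buffers, not parameters. When
#' `respect_masks = TRUE` and the model carries pruning masks, the count is
#' taken on the compacted model, i.e. masked channels are excluded.
#'
#' @param model a `slim3d_model`.
#' @param respect_masks exclude zero-masked channels from the count.
#' @return Integer parameter count.
#' @export
count_params <- function(model, respect_masks = FALSE) {
  stopifnot(inherits(model, "slim3d_model"))
  if (respect_masks && any_masked(model)) model <- compact(model)
  total <- 0
  for (l in model$layers)
    for (p in l$params) total <- total + length(p)
  as.integer(total)
}

any_masked <- function(model) {
  any(vapply(model$layers, function(l)
    identical(l$type, "batchnorm") && isTRUE(l$prunable) && !all(l$mask),
    logical(1)))
}

#' Count floating-point operations of a forward pass
#'
#' Per layer, `2 x out_positions x C_in x K^3 x C_out` for convolutions (a
#' multiply-add counts as two operations; depthwise convolutions use one
#' output channel per group and the per-group counts are summed; dilation
#' does not change the count) and `2 x m x n` for fully connected layers.
#' Batch normalization, activations, pooling, the attention module's
#' elementwise work and the small fusion-gate MLP are excluded from the
#' total, as is conventional for convolutional profilers.
#'
#' @param model a `slim3d_model`.
#' @param input_shape input geometry, (channels, depth, height, width);
#'   defaults to the model configuration's.
#' @param respect_masks exclude zero-masked channels.
#' @return FLOPs as a double (counts exceed 32-bit integer range).
#' @export
count_flops <- function(model, input_shape = model$config$input_shape,
                        respect_masks = FALSE) {
  stopifnot(inherits(model, "slim3d_model"))
  if (respect_masks && any_masked(model)) model <- compact(model)
  if (length(input_shape) != 4L)
    stop("`input_shape` must be (channels, depth, height, width)")
  shp <- as.integer(input_shape)   # C, D, H, W
  flops <- 0
  for (l in model$layers) {
    switch(l$type,
      pointwise = {
        cin <- ncol(l$params$W); cout <- nrow(l$params$W)
        if (shp[1] != cin)
          stop("input shape incompatible at a pointwise layer: expected ",
               cin, " channels, found ", shp[1])
        flops <- flops + 2 * prod(shp[2:4]) * cin * cout
        shp[1] <- cout
      },
      depthwise = {
        k <- dim(l$params$W)[1]
        newdims <- vapply(shp[2:4], conv_out_len, integer(1), k = k,
                          stride = l$stride, dilation = l$dilation,
                          pad = l$pad)
        if (any(newdims < 1L)) stop("input too small for the model")
        flops <- flops + 2 * prod(newdims) * k^3 * shp[1]
        shp[2:4] <- newdims
      },
      lmf = {
        cin <- shp[1]
        cout <- nrow(l$params$pw1)
        for (i in seq_along(l$scales)) {
          k <- l$scales[i]
          flops <- flops + 2 * prod(shp[2:4]) * k^3 * cin   # depthwise branch
          flops <- flops + 2 * prod(shp[2:4]) * cin * cout  # pointwise branch
        }
        shp[1] <- cout
      },
      dense = {
        flops <- flops + 2 * ncol(l$params$W) * nrow(l$params$W)
        shp[1] <- nrow(l$params$W)
      },
      NULL)   # batchnorm / relu / ils / gap excluded
  }
  flops
}

#' Model size from a parameter count
#'
#' `bytes = para * b`; the mebibyte figure divides by 2^20 (4-byte floats by
#' default).
#'
#' @param para non-negative parameter count.
#' @param b bytes per parameter.
#' @return List with `bytes` and `mib`.
#' @export
model_size <- function(para, b = 4L) {
  if (para < 0 || b < 1) stop("`para` must be >= 0 and `b` >= 1")
  bytes <- as.double(para) * b
  list(bytes = bytes, mib = bytes / 2^20)
}

#' Performance density
#'
#' Classification accuracy (on the 0-100 percent scale) per million
#' parameters: `acc_percent / (para / 1e6)`.
#'
#' @param acc_percent accuracy in percent.
#' @param para positive parameter count.
#' @return The performance density, in percent per million parameters.
#' @export
performance_density <- function(acc_percent, para) {
  if (para <= 0) stop("`para` must be > 0")
  acc_percent / (para / 1e6)
}

#' Full complexity report for a model
#'
#' @param model a `slim3d_model`.
#' @param input_shape input geometry for the FLOPs count.
#' @param acc_percent optional accuracy (0-100) enabling the performance
#'   density field.
#' @param bytes_per_param storage bytes per parameter.
#' @param respect_masks exclude zero-masked channels (default), so the report
#'   describes the compacted export of a pruned model.
#' @return An object of class `slim3d_complexity_report` (a named list with
#'   `para`, `flops`, `bytes_per_param`, `model_size_bytes`,
#'   `model_size_mib`, and optionally `acc_percent`, `pd`).
#' @export
complexity_report <- function(model, input_shape = model$config$input_shape,
                              acc_percent = NULL, bytes_per_param = 4L,
                              respect_masks = TRUE) {
  if (respect_masks && any_masked(model)) model <- compact(model)
  para <- count_params(model)
  flops <- count_flops(model, input_shape)
  ms <- model_size(para, bytes_per_param)
  rep <- list(para = para, flops = flops,
              bytes_per_param = as.integer(bytes_per_param),
              model_size_bytes = ms$bytes, model_size_mib = ms$mib,
              input_shape = as.integer(input_shape))
  if (!is.null(acc_percent)) {
    rep$acc_percent <- acc_percent
    rep$pd <- performance_density(acc_percent, para)
  }
  structure(rep, class = "slim3d_complexity_report")
}

#' @export
print.slim3d_complexity_report <- function(x, ...) {
  cat(sprintf("parameters : %s\n", format(x$para, big.mark = ",")))
  cat(sprintf("FLOPs      : %s  (input %s)\n",
              format(x$flops, big.mark = ","),
              paste(x$input_shape, collapse = "x")))
  cat(sprintf("model size : %.0f bytes (%.2f MiB at %d B/param)\n",
              x$model_size_bytes, x$model_size_mib, x$bytes_per_param))
  if (!is.null(x$pd))
    cat(sprintf("PD         : %.2f %% per million parameters (ACC %.2f%%)\n",
                x$pd, x$acc_percent))
  invisible(x)
}

#' Calibrate the width multiplier against a parameter budget
#'
#' Grid search over the width multiplier of [default_network_config()],
#' returning the multiplier whose unpruned parameter count is closest to the
#' target budget. This is how the packaged default multiplier was fixed.
#'
#' @param target_params parameter budget.
#' @param multipliers candidate grid.
#' @return List with the chosen `multiplier`, its `para`, and the full grid.
#' @export
calibrate_width_multiplier <- function(target_params = 0.92e6,
                                       multipliers = seq(1.6, 2.3, by = 0.05)) {
  paras <- vapply(multipliers, function(m)
    count_params(build_network(default_network_config(width_multiplier = m),
                               seed = 1L)), integer(1))
  i <- which.min(abs(paras - target_params))
  list(multiplier = multipliers[i], para = paras[i],
       grid = data.frame(multiplier = multipliers, para = paras))
}

#' Calibrate the prune target against a parameter budget
#'
#' Runs the progressive schedule on full-size models whose channel scales are
#' drawn from a half-normal distribution (emulating the spread that L1
#' regularization produces during training), compacts at a grid of
#' channel-removal targets, and returns the target whose mean compacted
#' parameter count is closest to the budget. This is how the packaged default
#' prune target was fixed.
#'
#' @param target_params parameter budget for the compacted model.
#' @param targets candidate channel-removal fractions.
#' @param n_rep random-scale replicates per candidate.
#' @param seed seed for the replicate scales.
#' @return List with the chosen `target`, its mean `para`, and the grid.
#' @export
calibrate_prune_target <- function(target_params = 0.49e6,
                                   targets = seq(0.16, 0.34, by = 0.02),
                                   n_rep = 3L, seed = 1L) {
  base <- build_network(default_network_config(), seed = seed)
  paras <- vapply(targets, function(tg) {
    mean(vapply(seq_len(n_rep), function(r) {
      m <- randomize_gammas(base, seed = derive_seed(seed, r))
      sch <- prune_schedule(target_total_fraction = tg)
      repeat {
        before <- m$prune$step_count
        m <- prune_step(m, sch)
        if (m$prune$step_count == before) break
      }
      count_params(compact(m))
    }, numeric(1)))
  }, numeric(1))
  i <- which.min(abs(paras - target_params))
  list(target = targets[i], para = paras[i],
       grid = data.frame(target = targets, para = paras))
}

# draw fresh half-normal channel scales for every prunable batch norm;
# used to emulate a trained scale distribution when profiling the pruning
# pipeline without a full training run
randomize_gammas <- function(model, seed = 1L) {
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(as.integer(seed))
  for (n in prunable_bn_names(model)) {
    C <- length(model$layers[[n]]$params$gamma)
    model$layers[[n]]$params$gamma <- abs(rnorm(C, 0, 0.5))
  }
  model
}
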