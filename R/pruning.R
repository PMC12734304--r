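# Progressive channel pruning driven by batch-normalization scale
# magnitudes. Channels whose |gamma| falls strictly below a global
# nearest-rank-lower quantile of the pooled remaining magnitudes are
# zero-masked during training and physically removed at export.

# prune-target channel fraction of the default schedule, chosen by
# calibrate_prune_target() so the compacted full-size model lands on the
# published 0.49 M parameter budget (about a 47% parameter reduction)
PRUNE_TARGET_DEFAULT <- 0.34

#' Pruning schedule
#'
#' @param interval_epochs prune every this many epochs during training.
#' @param ratio_per_step fraction of the currently remaining unprotected
#'   channels considered at each step (the step quantile).
#' @param target_total_fraction stop pruning once this cumulative fraction of
#'   the initially prunable channels has been removed.
#' @param protected_layers names of batch-norm layers that must never be
#'   pruned (the stem, classifier head and fusion-gate layers are structurally
#'   protected regardless).
#' @param per_layer if `TRUE`, the quantile threshold is computed per layer
#'   instead of over the global pool.
#' @return An object of class `slim3d_prune_schedule`.
#' @export
prune_schedule <- function(interval_epochs = 5L, ratio_per_step = 0.05,
                           target_total_fraction = PRUNE_TARGET_DEFAULT,
                           protected_layers = character(),
                           per_layer = FALSE) {
  if (ratio_per_step <= 0 || ratio_per_step >= 1)
    stop("`ratio_per_step` must lie in (0, 1)")
  if (target_total_fraction < 0 || target_total_fraction >= 1)
    stop("`target_total_fraction` must lie in [0, 1)")
  structure(list(interval_epochs = as.integer(interval_epochs),
                 ratio_per_step = ratio_per_step,
                 target_total_fraction = target_total_fraction,
                 protected_layers = protected_layers,
                 per_layer = per_layer),
            class = "slim3d_prune_schedule")
}

new_prune_state <- function(layers) {
  total <- sum(vapply(layers, function(l)
    if (identical(l$type, "batchnorm") && isTRUE(l$prunable))
      length(l$mask) else 0L, integer(1)))
  list(initial_total = total, step_count = 0L,
       cumulative_pruned_fraction = 0)
}

prunable_bn_names <- function(model, schedule = NULL) {
  nm <- names(model$layers)
  keep <- vapply(nm, function(n) {
    l <- model$layers[[n]]
    identical(l$type, "batchnorm") && isTRUE(l$prunable) &&
      (is.null(schedule) || !(n %in% schedule$protected_layers))
  }, logical(1))
  nm[keep]
}

#' Inspect the pruning state of a model
#'
#' @param model a `slim3d_model`.
#' @return A list with `gamma_by_layer`, `keep_mask`, `step_count`,
#'   `cumulative_pruned_fraction`.
#' @export
prune_state <- function(model) {
  nms <- prunable_bn_names(model)
  list(gamma_by_layer = lapply(stats::setNames(nms, nms),
                               function(n) model$layers[[n]]$params$gamma),
       keep_mask = lapply(stats::setNames(nms, nms),
                          function(n) model$layers[[n]]$mask),
       step_count = model$prune$step_count,
       cumulative_pruned_fraction = model$prune$cumulative_pruned_fraction)
}

#' L1 sparsity penalty on batch-normalization scales
#'
#' The regularizer added to the training loss: `lam * sum(|gamma|)` over all
#' prunable batch-norm channels. Its subgradient `lam * sign(gamma)` drives
#' unimportant channel scales toward zero so that the quantile projection can
#' identify them.
#'
#' @param gammas numeric vector, or list of numeric vectors, of channel
#'   scales.
#' @param lam non-negative regularization weight.
#' @return The scalar penalty.
#' @export
sparsity_penalty <- function(gammas, lam = 1e-4) {
  if (lam < 0) stop("`lam` must be >= 0")
  lam * sum(abs(unlist(gammas, use.names = FALSE)))
}

#' Quantile threshold for channel pruning
#'
#' The nearest-rank lower `r`-quantile of the pooled channel-scale
#' magnitudes: with the magnitudes sorted ascending, the threshold is the
#' value at rank `max(1, floor(r * n))`. Channels are pruned when their
#' magnitude is strictly below the threshold, so a level of 0 prunes nothing and
#' ties at the threshold are kept.
#'
#' @param gammas numeric vector of (pooled) channel scales; magnitudes are
#'   taken internally.
#' @param r quantile level in `[0, 1)`.
#' @return The scalar threshold tau.
#' @export
compute_threshold <- function(gammas, r) {
  if (r < 0 || r >= 1) stop("quantile level `r` must lie in [0, 1)")
  g <- sort(abs(unlist(gammas, use.names = FALSE)))
  if (!length(g)) stop("no channels available for thresholding")
  g[max(1L, floor(r * length(g)))]
}

# map from each prunable batch-norm layer to the weight slices its mask
# governs: the producing pointwise rows and every downstream consumer slice
prune_plan <- function(model) {
  nm <- names(model$layers)
  plan <- list()
  producer <- NULL   # name of the prunable bn currently owning the channels
  for (n in nm) {
    l <- model$layers[[n]]
    if (identical(l$type, "depthwise") && !is.null(producer)) {
      plan[[producer]]$consumers <-
        c(plan[[producer]]$consumers, list(list(layer = n, role = "dw")))
      pw_name <- sub("\\.dw$", ".pw", n)
      plan[[producer]]$consumers <-
        c(plan[[producer]]$consumers, list(list(layer = pw_name,
                                                role = "pw_cols")))
    }
    if (identical(l$type, "batchnorm") && isTRUE(l$prunable)) {
      plan[[n]] <- list(own_pw = sub("\\.bn$", ".pw", n), consumers = list())
      producer <- n
    }
    if (identical(l$type, "lmf")) {
      if (!is.null(producer))
        plan[[producer]]$consumers <-
          c(plan[[producer]]$consumers, list(list(layer = n, role = "lmf_in")))
      producer <- NULL   # fusion output channels are structurally protected
    }
    if (identical(l$type, "dense") && !is.null(producer)) {
      plan[[producer]]$consumers <-
        c(plan[[producer]]$consumers, list(list(layer = n,
                                                role = "dense_cols")))
    }
  }
  plan
}

# zero every weight slice governed by a FALSE mask entry (W' = W * indicator)
apply_masks <- function(model) {
  plan <- prune_plan(model)
  for (bn in names(plan)) {
    mask <- model$layers[[bn]]$mask
    if (all(mask)) next
    model$layers[[bn]]$params$gamma[!mask] <- 0
    model$layers[[bn]]$params$beta[!mask] <- 0
    own <- plan[[bn]]$own_pw
    model$layers[[own]]$params$W[!mask, ] <- 0
    for (cons in plan[[bn]]$consumers) {
      lay <- model$layers[[cons$layer]]
      switch(cons$role,
        dw = { model$layers[[cons$layer]]$params$W[, , , !mask] <- 0 },
        pw_cols = { model$layers[[cons$layer]]$params$W[, !mask] <- 0 },
        dense_cols = { model$layers[[cons$layer]]$params$W[, !mask] <- 0 },
        lmf_in = {
          for (i in seq_along(lay$scales)) {
            model$layers[[cons$layer]]$params[[paste0("dw", i)]][, , , !mask] <- 0
            model$layers[[cons$layer]]$params[[paste0("pw", i)]][, !mask] <- 0
          }
        })
    }
  }
  model
}

#' Apply one progressive pruning step
#'
#' Pools the scale magnitudes of all currently unmasked, unprotected
#' batch-norm channels, computes the nearest-rank-lower quantile at the
#' schedule's per-step ratio, and masks every channel strictly below it
#' (keeping at least one channel per layer). Masked channels have their
#' batch-norm scale/shift and the dependent convolution slices zeroed. If the
#' cumulative removed fraction has already reached the schedule target the
#' model is returned unchanged.
#'
#' @param model a `slim3d_model`.
#' @param schedule a [prune_schedule()].
#' @return The updated model (with `model$prune` advanced).
#' @export
prune_step <- function(model, schedule) {
  stopifnot(inherits(model, "slim3d_model"),
            inherits(schedule, "slim3d_prune_schedule"))
  st <- model$prune
  if (st$cumulative_pruned_fraction >= schedule$target_total_fraction)
    return(model)
  nms <- prunable_bn_names(model, schedule)
  if (!length(nms)) return(model)
  groups <- if (schedule$per_layer) as.list(nms) else list(nms)
  for (grp in groups) {
    pooled <- unlist(lapply(grp, function(n) {
      l <- model$layers[[n]]
      abs(l$params$gamma[l$mask])
    }))
    if (!length(pooled)) next
    tau <- compute_threshold(pooled, schedule$ratio_per_step)
    for (n in grp) {
      l <- model$layers[[n]]
      drop <- l$mask & (abs(l$params$gamma) < tau)
      keep_after <- l$mask & !drop
      if (!any(keep_after)) {
        # never empty a layer: retain the strongest remaining channel
        best <- which(l$mask)[which.max(abs(l$params$gamma[l$mask]))]
        drop[best] <- FALSE
      }
      model$layers[[n]]$mask <- l$mask & !drop
    }
  }
  model <- apply_masks(model)
  remaining <- sum(vapply(prunable_bn_names(model), function(n)
    sum(model$layers[[n]]$mask), numeric(1)))
  model$prune$step_count <- st$step_count + 1L
  model$prune$cumulative_pruned_fraction <-
    1 - remaining / model$prune$initial_total
  model
}

#' Physically remove masked channels from a model
#'
#' Builds a new model in which every masked channel is deleted, together with
#' the dependent slices of downstream depthwise kernels, pointwise columns
#' and classifier-head columns. In evaluation mode the compacted model's
#' output equals the masked model's output (up to floating-point error).
#'
#' @param model a `slim3d_model`.
#' @return A compacted `slim3d_model` with all-true masks.
#' @export
compact <- function(model) {
  stopifnot(inherits(model, "slim3d_model"))
  out <- model
  keep <- TRUE   # keep-vector of the current input channels (stem input)
  nm <- names(model$layers)
  for (n in nm) {
    l <- model$layers[[n]]
    switch(l$type,
      pointwise = {
        bn_name <- sub("\\.(conv|pw)$", ".bn", n)
        bnl <- model$layers[[bn_name]]
        rows <- if (!is.null(bnl) && isTRUE(bnl$prunable)) bnl$mask
                else rep(TRUE, nrow(l$params$W))
        if (!any(rows)) stop("mask empties layer ", n)
        out$layers[[n]]$params$W <-
          l$params$W[rows, keep, drop = FALSE]
        keep <- rows
      },
      depthwise = {
        out$layers[[n]]$params$W <- l$params$W[, , , keep, drop = FALSE]
      },
      batchnorm = {
        for (p in c("gamma", "beta"))
          out$layers[[n]]$params[[p]] <- l$params[[p]][keep]
        for (b in c("running_mean", "running_var"))
          out$layers[[n]]$buffers[[b]] <- l$buffers[[b]][keep]
        out$layers[[n]]$mask <- rep(TRUE, sum(keep))
      },
      lmf = {
        for (i in seq_along(l$scales)) {
          out$layers[[n]]$params[[paste0("dw", i)]] <-
            l$params[[paste0("dw", i)]][, , , keep, drop = FALSE]
          out$layers[[n]]$params[[paste0("pw", i)]] <-
            l$params[[paste0("pw", i)]][, keep, drop = FALSE]
        }
        keep <- rep(TRUE, l$channels)
      },
      dense = {
        out$layers[[n]]$params$W <- l$params$W[, keep, drop = FALSE]
        keep <- rep(TRUE, nrow(l$params$W))
      },
      NULL)
  }
  # the stage after the fusion block keeps its configured width; record it
  out$config$stage_widths <- {
    sw <- out$config$stage_widths
    pr <- prunable_bn_names(out)
    for (n in pr) {
      s <- as.integer(sub("^stage(\\d+)\\.bn$", "\\1", n))
      sw[s] <- length(out$layers[[n]]$mask)
    }
    sw
  }
  out$prune <- new_prune_state(out$layers)
  out
}
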