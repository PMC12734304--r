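# Training harness: label-smoothed cross-entropy with an L1 penalty on
# prunable batch-norm scales, SGD with momentum and weight decay, gradient
# accumulation to an effective batch, loss-plateau learning-rate decay, and
# progressive pruning on a fixed epoch interval.

#' Training configuration
#'
#' @param epochs number of training epochs.
#' @param batch_size micro-batch size.
#' @param accumulation_steps micro-batches accumulated per optimizer update
#'   (effective batch = `batch_size * accumulation_steps`).
#' @param lr initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param label_smoothing smoothing weight of the cross-entropy target.
#' @param sparsity_lambda L1 weight on prunable batch-norm scales.
#' @param plateau_factor multiplicative learning-rate decay on plateau.
#' @param plateau_patience epochs without training-loss improvement before
#'   decaying.
#' @param augment apply Gaussian-noise and gamma augmentation to training
#'   samples.
#' @param augment_noise_sd noise standard deviation of the augmentation.
#' @param augment_gamma_range range of the uniform gamma-correction exponent.
#' @param seed master seed of the run.
#' @return An object of class `slim3d_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 4L,
                         accumulation_steps = 4L, lr = 0.005,
                         momentum = 0.9, weight_decay = 1e-4,
                         label_smoothing = 0.1, sparsity_lambda = 1e-4,
                         plateau_factor = 0.1, plateau_patience = 10L,
                         augment = TRUE, augment_noise_sd = 0.01,
                         augment_gamma_range = c(0.8, 1.25), seed = 1L) {
  if (lr < 0 || momentum < 0 || weight_decay < 0 || sparsity_lambda < 0)
    stop("rates must be non-negative")
  if (label_smoothing < 0 || label_smoothing >= 1)
    stop("`label_smoothing` must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 accumulation_steps = as.integer(accumulation_steps),
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 label_smoothing = label_smoothing,
                 sparsity_lambda = sparsity_lambda,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 augment = augment, augment_noise_sd = augment_noise_sd,
                 augment_gamma_range = augment_gamma_range,
                 seed = as.integer(seed)),
            class = "slim3d_train_config")
}

#' Label-smoothed cross-entropy loss
#'
#' Cross-entropy of the softmax of the scores against the smoothed target
#' `q = (1 - eps) * onehot(label) + eps / K`, mean-reduced over the batch.
#' `eps = 0` recovers the standard cross-entropy.
#'
#' @param scores K x N score matrix (a vector is one sample).
#' @param labels integer class labels, 0-based, length N.
#' @param epsilon smoothing weight in `[0, 1)`.
#' @return The scalar loss.
#' @export
label_smoothing_loss <- function(scores, labels, epsilon = 0.1) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  smoothed_ce(scores, as.integer(labels), epsilon)$loss
}

# loss and score-gradient in one pass
smoothed_ce <- function(scores, labels, epsilon) {
  K <- nrow(scores); N <- ncol(scores)
  if (epsilon < 0 || epsilon >= 1) stop("`epsilon` must lie in [0, 1)")
  m <- apply(scores, 2, max)
  e <- exp(sweep(scores, 2, m))
  p <- sweep(e, 2, colSums(e), `/`)
  q <- matrix(epsilon / K, K, N)
  q[cbind(labels + 1L, seq_len(N))] <- 1 - epsilon + epsilon / K
  logp <- sweep(scores, 2, m + log(colSums(e)))
  list(loss = -sum(q * logp) / N, grad = (p - q) / N, prob = p)
}

# recursive gradient-accumulation helpers ------------------------------------

acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) a[[i]] <- Map(`+`, a[[i]], b[[i]])
  a
}

scale_grads <- function(g, s) lapply(g, function(l) lapply(l, `*`, s))

# one SGD-with-momentum update; weight decay is added to the gradient, the
# L1 subgradient on prunable batch-norm scales likewise
sgd_update <- function(model, vel, grads, cfg) {
  prunable <- prunable_bn_names(model)
  for (ln in names(model$layers)) {
    lg <- grads[[ln]]
    if (is.null(lg) || !length(lg)) next
    for (pn in names(lg)) {
      g <- lg[[pn]] + cfg$weight_decay * model$layers[[ln]]$params[[pn]]
      if (ln %in% prunable && pn == "gamma")
        g <- g + cfg$sparsity_lambda * sign(model$layers[[ln]]$params[[pn]])
      key <- paste(ln, pn, sep = "/")
      v <- if (is.null(vel[[key]])) g else cfg$momentum * vel[[key]] + g
      vel[[key]] <- v
      model$layers[[ln]]$params[[pn]] <-
        model$layers[[ln]]$params[[pn]] - cfg$lr * v
    }
  }
  list(model = model, vel = vel)
}

augment_array <- function(a, cfg) {
  a <- a + array(rnorm(length(a), 0, cfg$augment_noise_sd), dim(a))
  a <- pmin(pmax(a, 0), 1)
  g <- runif(1, cfg$augment_gamma_range[1], cfg$augment_gamma_range[2])
  a^g
}

#' Train a model
#'
#' Runs SGD with momentum and weight decay on the label-smoothed
#' cross-entropy plus the L1 batch-norm sparsity penalty, accumulating
#' gradients over micro-batches, decaying the learning rate when the training
#' loss plateaus, and (when a schedule is given) applying a progressive
#' pruning step on the schedule's epoch interval. Fully seeded: the same
#' configuration and data reproduce the same history.
#'
#' @param model a `slim3d_model`.
#' @param volumes list of [volume()]s or 3D arrays.
#' @param labels integer class labels (0-based), one per volume.
#' @param cfg a [train_config()].
#' @param schedule optional [prune_schedule()].
#' @param val_volumes,val_labels optional held-out set evaluated per epoch.
#' @param checkpoint_dir optional directory receiving one checkpoint per
#'   epoch.
#' @param verbose print a per-epoch summary line.
#' @return List with the trained `model`, a `history` data frame (epoch,
#'   train_loss, val_loss, train_acc, val_acc, lr, pruned_fraction) and the
#'   final `prune_state` view.
#' @export
train <- function(model, volumes, labels, cfg, schedule = NULL,
                  val_volumes = NULL, val_labels = NULL,
                  checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "slim3d_model"),
            inherits(cfg, "slim3d_train_config"))
  labels <- as.integer(labels)
  n <- length(volumes)
  if (n < cfg$batch_size) stop("fewer samples than one micro-batch")
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "slim3d_volume")) v$data else v)
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(derive_seed(cfg$seed, 7L))
  vel <- list()
  lr <- cfg$lr
  best_loss <- Inf
  stall <- 0L
  hist <- vector("list", cfg$epochs)
  cfg_step <- cfg
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  for (epoch in seq_len(cfg$epochs)) {
    prev_model <- model
    order <- sample.int(n)
    acc <- NULL
    n_acc <- 0L
    epoch_loss <- 0
    epoch_correct <- 0L
    nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      idx <- order[i:j]
      batch <- lapply(arrs[idx], function(a)
        if (cfg$augment) augment_array(a, cfg) else a)
      x <- volumes_to_batch(batch)
      fw <- model_forward(model, x, training = TRUE, keep_cache = TRUE)
      model <- fw$model
      ce <- smoothed_ce(fw$scores, labels[idx], cfg$label_smoothing)
      g <- model_backward(model, fw$caches, ce$grad)
      acc <- acc_grads(acc, g)
      n_acc <- n_acc + 1L
      epoch_loss <- epoch_loss + ce$loss
      nb <- nb + 1L
      epoch_correct <- epoch_correct +
        sum(max.col(t(ce$prob), ties.method = "first") - 1L == labels[idx])
      if (n_acc == cfg$accumulation_steps || j == n) {
        cfg_step$lr <- lr
        up <- sgd_update(model, vel, scale_grads(acc, 1 / n_acc), cfg_step)
        model <- up$model
        vel <- up$vel
        model <- apply_masks(model)
        acc <- NULL
        n_acc <- 0L
      }
      i <- j + 1L
    }
    penalty <- sparsity_penalty(
      lapply(prunable_bn_names(model),
             function(nm) model$layers[[nm]]$params$gamma),
      cfg$sparsity_lambda)
    train_loss <- epoch_loss / nb + penalty
    if (!is.finite(train_loss)) {
      warning("training diverged at epoch ", epoch,
              "; returning the last finite model")
      model <- prev_model
      break
    }
    val_loss <- NA_real_
    val_acc <- NA_real_
    if (!is.null(val_volumes)) {
      ev <- model_evaluate(model, val_volumes, as.integer(val_labels))
      val_acc <- ev$accuracy
      vs <- model_forward(model, volumes_to_batch(val_volumes))$scores
      val_loss <- smoothed_ce(vs, as.integer(val_labels),
                              cfg$label_smoothing)$loss
    }
    # learning-rate plateau scheduling on the training loss
    if (train_loss < best_loss * (1 - 1e-4)) {
      best_loss <- train_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        stall <- 0L
      }
    }
    if (!is.null(schedule) && epoch %% schedule$interval_epochs == 0L)
      model <- prune_step(model, schedule)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      train_acc = epoch_correct / n, val_acc = val_acc, lr = lr,
      pruned_fraction = model$prune$cumulative_pruned_fraction)
    if (!is.null(checkpoint_dir))
      save_checkpoint(model, file.path(checkpoint_dir,
                                       sprintf("epoch%03d.rds", epoch)))
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.3f  lr %.2g  pruned %.2f",
        epoch, train_loss, epoch_correct / n, lr,
        model$prune$cumulative_pruned_fraction))
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  list(model = model, history = history, prune_state = prune_state(model))
}
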