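# Evaluation statistics: confusion-matrix metrics, rank-based AUC, the
# one-sample t-test over cross-validation folds, and the subject-level
# stratified k-fold driver.

#' Subject-level stratified k-fold split
#'
#' Partitions subjects (not scans) into k folds, stratified by class: within
#' each class the shuffled subjects are dealt round-robin, so per-fold class
#' counts differ by at most one. All volumes of a subject share a fold,
#' preventing subject leakage between training and testing.
#'
#' @param manifest data frame with `subject_id` and `label` columns.
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return Integer vector of fold indices (1..k), one per manifest row.
#' @export
kfold_split <- function(manifest, k = 5L, seed = 1L) {
  subj <- manifest$subject_id[!duplicated(manifest$subject_id)]
  slab <- manifest$label[match(subj, manifest$subject_id)]
  for (cl in unique(slab))
    if (sum(slab == cl) < k)
      stop("need at least ", k, " subjects per class for a ", k, "-fold split")
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(as.integer(seed))
  fold_of <- integer(length(subj))
  names(fold_of) <- subj
  for (cl in sort(unique(slab))) {
    s <- sample(subj[slab == cl])
    fold_of[s] <- rep_len(seq_len(k), length(s))
  }
  unname(fold_of[manifest$subject_id])
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall of the positive class), specificity,
#' precision, recall and F1 from true/false positive/negative counts.
#' Metrics whose denominator is zero are reported as `NA` (undefined), never
#' coerced to 0.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return List with `acc`, `sen`, `spe`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  total <- tp + tn + fp + fn
  if (total < 1) stop("at least one observation is required")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  precision <- safe_div(tp, tp + fp)
  recall <- sen
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(acc = (tp + tn) / total, sen = sen, spe = spe,
       precision = precision, recall = recall, f1 = f1)
}

#' Area under the ROC curve (rank statistic)
#'
#' The Mann-Whitney formulation: the fraction of (positive, negative) pairs
#' whose scores are correctly ordered, ties counting one half. Computed from
#' midranks, which is exactly the pair statistic.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-sample t-test of fold accuracies against a baseline mean
#'
#' `t = (mean(x) - mu0) / (s / sqrt(n))` with the sample standard deviation
#' (n - 1 denominator) and a Student-t p-value on `n - 1` degrees of freedom.
#' The default alternative is the upper tail (improvement over the
#' baseline).
#'
#' @param x numeric vector of per-fold accuracies, length >= 2.
#' @param mu0 baseline mean accuracy.
#' @param alternative `"greater"` (one-sided upper tail) or `"two.sided"`.
#' @return An object of class `slim3d_ttest`: list with `mean`, `baseline`,
#'   `sd`, `n`, `df`, `t`, `p`, `alternative`.
#' @export
one_sample_ttest <- function(x, mu0, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (n < 2) stop("at least two folds are required")
  s <- sd(x)
  if (s == 0) stop("zero variance across folds; the t statistic is undefined")
  t <- (mean(x) - mu0) / (s / sqrt(n))
  p <- switch(alternative,
              greater = pt(t, df = n - 1, lower.tail = FALSE),
              two.sided = 2 * pt(-abs(t), df = n - 1))
  structure(list(mean = mean(x), baseline = mu0, sd = s, n = n, df = n - 1,
                 t = t, p = p, alternative = alternative),
            class = "slim3d_ttest")
}

#' @export
print.slim3d_ttest <- function(x, ...) {
  cat(sprintf("one-sample t-test (%s): t = %.3f, df = %d, p = %.4g\n",
              x$alternative, x$t, x$df, x$p))
  cat(sprintf("  mean %.4f vs baseline %.4f (sd %.4f, n %d)\n",
              x$mean, x$baseline, x$sd, x$n))
  invisible(x)
}

#' Cross-validated training and evaluation
#'
#' Subject-level stratified k-fold cross-validation. Within each fold the
#' training subset is class-balanced by [oversample_balance()] and (if
#' enabled in the training config) augmented; the held-out fold is evaluated
#' untouched. Returns per-fold metrics and their mean and standard deviation.
#'
#' @param cohort a `slim3d_cohort`.
#' @param net_cfg a [network_config()].
#' @param cfg a [train_config()].
#' @param schedule optional [prune_schedule()].
#' @param k number of folds.
#' @param keep_models retain each fold's trained model (memory permitting).
#' @param verbose print per-epoch progress.
#' @return List with `folds` (data frame: fold, acc, sen, spe, precision,
#'   f1, auc), `mean`, `sd`, `split`, and optionally `models` and
#'   `test_indices`.
#' @export
cross_validate <- function(cohort, net_cfg, cfg, schedule = NULL, k = 5L,
                           keep_models = FALSE, verbose = FALSE) {
  stopifnot(inherits(cohort, "slim3d_cohort"))
  fold <- kfold_split(cohort$manifest, k = k, seed = cfg$seed)
  rows <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  test_idx_all <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    stopifnot(length(intersect(cohort$manifest$subject_id[test_idx],
                               cohort$manifest$subject_id[train_idx])) == 0)
    bal <- oversample_balance(cohort$manifest[train_idx, , drop = FALSE],
                              seed = derive_seed(cfg$seed, 50L + f))
    tr_rows <- train_idx[bal]
    model <- build_network(net_cfg, seed = derive_seed(cfg$seed, 100L + f))
    fit <- train(model, cohort$volumes[tr_rows],
                 cohort$manifest$label[tr_rows], cfg, schedule,
                 verbose = verbose)
    ev <- model_evaluate(fit$model, cohort$volumes[test_idx],
                         cohort$manifest$label[test_idx])
    truth <- cohort$manifest$label[test_idx]
    cm <- confusion_metrics(tp = sum(ev$pred == 1 & truth == 1),
                            tn = sum(ev$pred == 0 & truth == 0),
                            fp = sum(ev$pred == 1 & truth == 0),
                            fn = sum(ev$pred == 0 & truth == 1))
    auc <- if (length(unique(truth)) == 2) roc_auc(ev$prob1, truth) else NA_real_
    rows[[f]] <- data.frame(fold = f, acc = cm$acc, sen = cm$sen,
                            spe = cm$spe, precision = cm$precision,
                            f1 = cm$f1, auc = auc)
    if (keep_models) models[[f]] <- fit$model
    test_idx_all[[f]] <- test_idx
    if (verbose)
      message(sprintf("fold %d/%d: acc %.3f", f, k, cm$acc))
  }
  folds <- do.call(rbind, rows)
  metric_cols <- setdiff(names(folds), "fold")
  res <- list(folds = folds,
              mean = colMeans(folds[metric_cols], na.rm = TRUE),
              sd = vapply(folds[metric_cols], sd, numeric(1), na.rm = TRUE),
              split = fold)
  if (keep_models) {
    res$models <- models
    res$test_indices <- test_idx_all
  }
  res
}
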