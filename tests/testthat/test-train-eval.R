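test_that("label smoothing loss matches its closed forms", {
  # eps = 0 is the plain cross-entropy
  sc <- matrix(c(1.2, -0.3, 0.4, 2.0), 2, 2)
  lab <- c(0L, 1L)
  ce_ref <- -mean(log(exp(sc[cbind(lab + 1, 1:2)]) / colSums(exp(sc))))
  expect_equal(label_smoothing_loss(sc, lab, epsilon = 0), ce_ref)

  # uniform scores: loss is ln 2 for any smoothing (two classes)
  u <- matrix(0, 2, 3)
  expect_equal(label_smoothing_loss(u, c(0L, 1L, 0L), 0.1), log(2))
  expect_equal(label_smoothing_loss(u, c(0L, 1L, 0L), 0.5), log(2))

  # eps = 0.1, K = 2, true-class probability 0.9
  s1 <- matrix(c(log(0.9), log(0.1)), 2, 1)
  expect_equal(label_smoothing_loss(s1, 0L, 0.1),
               -(0.95 * log(0.9) + 0.05 * log(0.1)))
})

test_that("a zero learning rate leaves parameters unchanged", {
  sp <- phantom_spec(shape = c(8, 10, 10), effect_size = 0.3,
                     signal_slab = c(2, 6), seed = 1)
  coh <- simulate_cohort(3, sp)
  cfg0 <- network_config(stage_widths = c(3, 4), stem_channels = 3,
                         stage_strides = c(2, 1), lmf_position = 1,
                         ils_positions = 2, dilation_rates = c(1, 2),
                         input_shape = c(1, 8, 10, 10))
  m <- build_network(cfg0, seed = 2)
  fit <- train(m, coh$volumes, coh$manifest$label,
               train_config(epochs = 1, lr = 0, accumulation_steps = 1,
                            weight_decay = 0, seed = 3))
  expect_identical(lapply(fit$model$layers, `[[`, "params"),
                   lapply(m$layers, `[[`, "params"))
})

test_that("training histories are reproducible from the seed", {
  sp <- phantom_spec(shape = c(8, 10, 10), effect_size = 0.4,
                     signal_slab = c(2, 6), seed = 5)
  coh <- simulate_cohort(4, sp)
  cfg0 <- network_config(stage_widths = c(3, 4), stem_channels = 3,
                         stage_strides = c(2, 1), lmf_position = 1,
                         ils_positions = 2, dilation_rates = c(1, 2),
                         input_shape = c(1, 8, 10, 10))
  cfg <- train_config(epochs = 2, lr = 0.01, seed = 11)
  f1 <- train(build_network(cfg0, 4), coh$volumes, coh$manifest$label, cfg)
  f2 <- train(build_network(cfg0, 4), coh$volumes, coh$manifest$label, cfg)
  expect_identical(f1$history, f2$history)
})

test_that("the k-fold split is a stratified subject-level partition", {
  man <- data.frame(subject_id = sprintf("S%02d", 1:10),
                    label = rep(c(0, 1), 5))
  f <- kfold_split(man, k = 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  # 50/50 mix: every fold within +-1 of balance
  for (i in 1:5) expect_lte(abs(sum(man$label[f == i]) - 1), 1)

  # multi-scan subjects stay in one fold
  man2 <- rbind(man, man[1:4, ])
  f2 <- kfold_split(man2, k = 5, seed = 2)
  for (s in unique(man2$subject_id))
    expect_length(unique(f2[man2$subject_id == s]), 1)

  expect_error(kfold_split(man[1:6, ], k = 5), "at least 5 subjects")
})

test_that("confusion metrics follow the printed formulas", {
  m <- confusion_metrics(tp = 3, tn = 2, fp = 1, fn = 0)
  expect_equal(m$acc, 5 / 6)
  expect_equal(m$sen, 1)
  expect_equal(m$spe, 2 / 3)

  perf <- confusion_metrics(tp = 4, tn = 6, fp = 0, fn = 0)
  expect_equal(unlist(perf[c("acc", "sen", "spe", "f1")]),
               c(acc = 1, sen = 1, spe = 1, f1 = 1))

  # harmonic mean of equal precision/recall
  pr <- confusion_metrics(tp = 9, tn = 9, fp = 1, fn = 1)
  expect_equal(pr$f1, 0.9)

  # undefined metrics are NA, not zero
  und <- confusion_metrics(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_true(is.na(und$sen))
  expect_true(is.na(und$precision))
})

test_that("the AUC equals brute-force pair enumeration", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    sc <- round(runif(n), 1)          # coarse scores force ties
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(sc, lab), oracle_auc_pairs(sc, lab))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("the fold t-test matches Student-t tail values", {
  # symmetric case
  x <- c(0.9, 0.8, 0.85, 0.95, 0.8)
  r0 <- one_sample_ttest(x, mu0 = mean(x))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)

  # published fold statistics: t = 4.15 on 4 df gives p = 0.007 (3 d.p.)
  expect_equal(round(pt(4.15, df = 4, lower.tail = FALSE), 3), 0.007)

  # direct evaluation of the statistic
  x2 <- c(0.9, 0.92, 0.94, 0.96, 0.93)   # mean .93, engineered below
  r2 <- one_sample_ttest(x2, 0.87)
  expect_equal(r2$t, (mean(x2) - 0.87) / (sd(x2) / sqrt(5)))
  expect_equal((0.93 - 0.87) / (0.02 / sqrt(5)), 6.708, tolerance = 1e-4)

  # textbook critical values on 4 df
  expect_equal(pt(3.747, 4, lower.tail = FALSE), 0.010, tolerance = 2e-4)
  expect_equal(pt(4.604, 4, lower.tail = FALSE), 0.005, tolerance = 2e-4)

  expect_error(one_sample_ttest(rep(0.9, 5), 0.85), "variance")
  expect_error(one_sample_ttest(0.9, 0.85), "two folds")

  r3 <- one_sample_ttest(x2, 0.87, alternative = "two.sided")
  expect_equal(r3$p, 2 * pt(-abs(r3$t), 4))
})

test_that("cross-validation never leaks test subjects and aggregates means", {
  sp <- phantom_spec(shape = c(8, 10, 10), effect_size = 0.5,
                     signal_slab = c(2, 6), seed = 31)
  coh <- simulate_cohort(5, sp)
  cfg0 <- network_config(stage_widths = c(3, 4), stem_channels = 3,
                         stage_strides = c(2, 1), lmf_position = 1,
                         ils_positions = 2, dilation_rates = c(1, 2),
                         input_shape = c(1, 8, 10, 10))
  cfg <- train_config(epochs = 1, lr = 0.01, seed = 13)
  cv <- cross_validate(coh, cfg0, cfg, k = 5)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(unname(cv$mean["acc"]), mean(cv$folds$acc))
  # partition: every subject in exactly one fold
  expect_equal(sort(unique(cv$split)), 1:5)
  expect_length(cv$split, nrow(coh$manifest))
})
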