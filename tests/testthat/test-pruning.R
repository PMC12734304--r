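test_that("the sparsity penalty is an L1 norm scaled by lambda", {
  expect_equal(sparsity_penalty(c(0, 0, 0), 1e-4), 0)
  expect_equal(sparsity_penalty(c(1, -1), 1e-4), 2e-4)
  g <- list(a = c(0.3, -0.2), b = 0.5)
  expect_equal(sparsity_penalty(g, 2e-4), 2 * sparsity_penalty(g, 1e-4))
})

test_that("the threshold is the nearest-rank lower quantile", {
  g <- c(0.05, 0.1, 0.5, 0.9)
  expect_equal(compute_threshold(g, 0.5), 0.1)
  expect_true(all(abs(g)[abs(g) < compute_threshold(g, 0.5)] == 0.05))
  # level 0 never prunes
  expect_lte(compute_threshold(g, 0), min(abs(g)))
  expect_length(g[abs(g) < compute_threshold(g, 0)], 0)
  # all-equal magnitudes: ties are kept
  ge <- rep(0.3, 6)
  expect_length(ge[abs(ge) < compute_threshold(ge, 0.5)], 0)
  expect_error(compute_threshold(g, 1), "\\[0, 1\\)")
})

prunable_masked_model <- function(seed = 1, widths = c(6, 8, 8)) {
  cfg <- network_config(stage_widths = widths, stem_channels = 4,
                        stage_strides = c(2, rep(1, length(widths) - 1)),
                        lmf_position = 2, ils_positions = length(widths),
                        dilation_rates = c(1, 2),
                        input_shape = c(1, 8, 10, 10))
  slim3d:::randomize_gammas(build_network(cfg, seed = seed), seed = seed + 50)
}

test_that("prune_step implements the strict-inequality quantile projection", {
  m <- prunable_masked_model(2)
  sch <- prune_schedule(ratio_per_step = 0.25, target_total_fraction = 0.6)
  pooled <- unlist(lapply(slim3d:::prunable_bn_names(m), function(n)
    abs(m$layers[[n]]$params$gamma)))
  tau <- compute_threshold(pooled, 0.25)
  m2 <- prune_step(m, sch)
  for (n in slim3d:::prunable_bn_names(m2)) {
    gam <- m$layers[[n]]$params$gamma       # pre-pruning scales
    mask <- m2$layers[[n]]$mask
    # exactness: kept <=> |gamma| >= tau (keep-one rule only when a layer
    # would otherwise be emptied)
    if (any(abs(gam) >= tau)) {
      expect_equal(mask, abs(gam) >= tau, info = n)
    } else {
      expect_equal(sum(mask), 1, info = n)
    }
    # masked channels have their bn scale/shift zeroed
    expect_true(all(m2$layers[[n]]$params$gamma[!mask] == 0))
    expect_true(all(m2$layers[[n]]$params$beta[!mask] == 0))
  }
  # newly masked count is bounded by the step ratio of remaining channels
  removed <- sum(!unlist(lapply(slim3d:::prunable_bn_names(m2), function(n)
    m2$layers[[n]]$mask)))
  expect_lte(removed, floor(0.25 * length(pooled)))
})

test_that("pruning stops at the target and is idempotent there", {
  m <- prunable_masked_model(3)
  sch <- prune_schedule(ratio_per_step = 0.3, target_total_fraction = 0.3)
  m1 <- prune_step(m, sch)
  expect_gt(m1$prune$cumulative_pruned_fraction, 0)
  m2 <- prune_step(m1, sch)   # target reached after step 1
  if (m1$prune$cumulative_pruned_fraction >= 0.3) {
    expect_identical(m2, m1)
  }
  m3 <- prune_step(m2, sch)
  expect_identical(m3, m2)
})

test_that("masks never return and follow the compounding schedule", {
  m <- prunable_masked_model(4, widths = c(8, 12, 16))
  sch <- prune_schedule(ratio_per_step = 0.2, target_total_fraction = 0.9)
  prev <- prune_state(m)$keep_mask
  total0 <- sum(lengths(prev))
  for (s in 1:4) {
    m <- prune_step(m, sch)
    cur <- prune_state(m)$keep_mask
    for (n in names(cur)) expect_true(all(prev[[n]] >= cur[[n]]))
    prev <- cur
    remaining <- sum(unlist(cur))
    # nearest-rank flooring keeps the remaining count within one channel of
    # the ideal geometric decay
    expect_lte(abs(remaining - total0 * (1 - 0.2)^s), s + 1)
    # every layer keeps at least one channel
    expect_true(all(vapply(cur, sum, numeric(1)) >= 1))
  }
})

test_that("masked and compacted models are forward-equivalent", {
  for (seed in 1:20) {
    cfg <- random_tiny_config(seed)
    m <- build_network(cfg, seed = seed)
    m <- slim3d:::randomize_gammas(m, seed = seed + 100)
    m <- prune_step(m, prune_schedule(ratio_per_step = 0.3,
                                      target_total_fraction = 0.8))
    mc <- compact(m)
    x <- rand_input(cfg$input_shape, n = 2L, seed = seed)
    y_masked <- slim3d:::model_forward(m, x)$scores
    y_comp <- slim3d:::model_forward(mc, x)$scores
    expect_lt(max(abs(y_masked - y_comp) / (abs(y_masked) + 1e-3)), 1e-5,
              label = sprintf("architecture seed %d", seed))
    expect_lte(count_params(mc), count_params(m))
    expect_equal(count_params(mc), count_params(m, respect_masks = TRUE))
  }
})

test_that("compaction is a no-op on unmasked models and monotone under steps", {
  m <- prunable_masked_model(6)
  mc <- compact(m)
  expect_equal(count_params(mc), count_params(m))
  x <- array(runif(8 * 10 * 10), c(1, 8, 10, 10, 1))
  expect_equal(slim3d:::model_forward(mc, x)$scores,
               slim3d:::model_forward(m, x)$scores, tolerance = 1e-12)

  sch <- prune_schedule(ratio_per_step = 0.15, target_total_fraction = 0.8)
  paras <- count_params(m)
  for (s in 1:3) {
    m <- prune_step(m, sch)
    p <- count_params(compact(m))
    expect_lte(p, paras[length(paras)])
    paras <- c(paras, p)
  }

  # complexity report of a compacted model never exceeds the original
  rep0 <- complexity_report(prunable_masked_model(6))
  rep1 <- complexity_report(m)
  for (f in c("para", "flops", "model_size_bytes", "model_size_mib"))
    expect_lte(rep1[[f]], rep0[[f]])
})

test_that("masked training keeps pruned channels at exactly zero", {
  m <- prunable_masked_model(8)
  m <- prune_step(m, prune_schedule(ratio_per_step = 0.3,
                                    target_total_fraction = 0.5))
  sp <- phantom_spec(shape = c(8, 10, 10), effect_size = 0.3,
                     signal_slab = c(2, 6), seed = 1)
  coh <- simulate_cohort(4, sp)
  cfg <- train_config(epochs = 2, batch_size = 4, accumulation_steps = 1,
                      lr = 0.01, seed = 1)
  fit <- train(m, coh$volumes, coh$manifest$label, cfg)
  for (n in slim3d:::prunable_bn_names(fit$model)) {
    mask <- fit$model$layers[[n]]$mask
    expect_true(all(fit$model$layers[[n]]$params$gamma[!mask] == 0))
    pw <- sub("\\.bn$", ".pw", n)
    expect_true(all(fit$model$layers[[pw]]$params$W[!mask, ] == 0))
  }
})
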