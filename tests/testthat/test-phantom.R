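spec_small <- phantom_spec(shape = c(24, 20, 20), effect_size = 0.2,
                           signal_slab = c(8, 16), noise_sd = 0.05,
                           smoothing_sigma = 1, seed = 11)

test_that("phantom generation is deterministic and label-blind at zero effect", {
  v1 <- generate_phantom(0, spec_small, draw = 3)
  v2 <- generate_phantom(0, spec_small, draw = 3)
  expect_identical(v1$data, v2$data)

  # noiseless generator is bit-identical too
  s0 <- phantom_spec(shape = c(10, 12, 12), effect_size = 0.3,
                     signal_slab = c(3, 7), noise_sd = 0, smoothing_sigma = 0,
                     seed = 2)
  expect_identical(generate_phantom(1, s0, draw = 5)$data,
                   generate_phantom(1, s0, draw = 5)$data)

  # effect_size = 0: class-conditional distributions identical
  snull <- phantom_spec(shape = c(24, 20, 20), effect_size = 0,
                        signal_slab = c(8, 16), seed = 11)
  expect_identical(generate_phantom(0, snull, draw = 1)$data,
                   generate_phantom(1, snull, draw = 1)$data)

  # different draws differ
  expect_false(identical(generate_phantom(0, spec_small, draw = 1)$data,
                         generate_phantom(0, spec_small, draw = 2)$data))
})

test_that("phantoms are normalized and reject bad shapes", {
  v <- generate_phantom(1, spec_small, draw = 0)
  expect_true(all(is.finite(v$data)))
  expect_gte(min(v$data), 0)
  expect_lte(max(v$data), 1)
  expect_error(phantom_spec(shape = c(0, 8, 8)), "positive")
  expect_error(phantom_spec(shape = c(8, 8, 8), signal_slab = c(4, 10)),
               "signal_slab")
})

test_that("signal-region intensity decreases monotonically with effect size", {
  masks <- slim3d:::phantom_masks(spec_small)
  means <- vapply(c(0.1, 0.2, 0.4), function(es) {
    sp <- phantom_spec(shape = c(24, 20, 20), effect_size = es,
                       signal_slab = c(8, 16), noise_sd = 0.05,
                       smoothing_sigma = 1, seed = 11)
    mean(generate_phantom(1, sp, draw = 4)$data[masks$signal])
  }, numeric(1))
  expect_true(all(diff(means) < 0))

  # classifier-free class contrast grows with effect size
  contrast <- vapply(c(0.1, 0.3), function(es) {
    sp <- phantom_spec(shape = c(24, 20, 20), effect_size = es,
                       signal_slab = c(8, 16), seed = 5)
    m0 <- mean(sapply(0:3, function(d)
      mean(generate_phantom(0, sp, d)$data[masks$signal])))
    m1 <- mean(sapply(0:3, function(d)
      mean(generate_phantom(1, sp, d)$data[masks$signal])))
    m0 - m1
  }, numeric(1))
  expect_gt(contrast[2], contrast[1])
})

test_that("gaussian noise augmentation matches its nominal scale", {
  base <- volume(array(0.5, c(73, 96, 96)))
  expect_identical(augment_gaussian_noise(base, sd = 0)$data, base$data)
  out <- augment_gaussian_noise(base, sd = 0.01, seed = 4)
  # intensities sit mid-range, so clipping never triggers here
  expect_lt(abs(sd(out$data - base$data) - 0.01) / 0.01, 0.05)
  out2 <- augment_gaussian_noise(base, sd = 0.01, seed = 5)
  expect_false(identical(out$data, out2$data))
  expect_error(augment_gaussian_noise(base, sd = -1), ">= 0")
  expect_true(all(augment_gaussian_noise(base, 0.5, 1)$data >= 0))
})

test_that("gamma correction is exact and monotone", {
  v <- volume(array(c(0.5, 0.1, 0.9, 0.3), c(1, 2, 2)))
  expect_identical(augment_gamma(v, 1)$data, v$data)
  expect_equal(augment_gamma(v, 2)$data[1, 1, 1], 0.25)
  expect_identical(order(augment_gamma(v, 0.5)$data), order(v$data))
  expect_error(augment_gamma(v, 0), "> 0")
})

test_that("oversampling balances classes with majority kept once", {
  man <- data.frame(subject_id = sprintf("S%02d", 1:20),
                    label = rep(c(0, 1), each = 10))
  idx <- oversample_balance(man, seed = 1)
  expect_equal(sort(idx), 1:20)

  man2 <- data.frame(subject_id = sprintf("S%02d", 1:14),
                     label = rep(c(0, 1), c(10, 4)))
  idx2 <- oversample_balance(man2, seed = 1)
  expect_length(idx2, 20)
  expect_equal(sum(man2$label[idx2] == 0), 10)
  expect_equal(sum(man2$label[idx2] == 1), 10)
  expect_true(all(table(idx2[man2$label[idx2] == 0]) == 1))

  man3 <- data.frame(subject_id = c("a", "b", "c", "d"),
                     label = c(0, 0, 0, 1))
  idx3 <- oversample_balance(man3, seed = 2)
  expect_equal(sum(idx3 == 4), 3)
  expect_error(oversample_balance(data.frame(label = c(0, 0))), "both classes")
})

test_that("cohorts round-trip through NIfTI within float32 precision", {
  sp <- phantom_spec(shape = c(10, 12, 12), effect_size = 0.3,
                     signal_slab = c(3, 7), seed = 9)
  coh <- simulate_cohort(1, sp)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_true(all(file.exists(man$path)))
  back <- read_cohort(dir)
  expect_equal(back$manifest$label, coh$manifest$label)
  for (i in seq_along(coh$volumes))
    expect_equal(back$volumes[[i]]$data, coh$volumes[[i]]$data,
                 tolerance = 1e-6)

  # a missing file is named in the error
  man2 <- read.csv(file.path(dir, "manifest.csv"))
  man2$path[1] <- file.path(dir, "missing.nii.gz")
  write.csv(man2, file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "missing.nii.gz")

  # empty directory: warning plus empty manifest
  empty <- withr::local_tempdir()
  expect_warning(out <- read_cohort(empty), "empty")
  expect_equal(nrow(out$manifest), 0)
})

test_that("cohort simulation is a pure function of spec and size", {
  sp <- phantom_spec(shape = c(8, 10, 10), effect_size = 0.2,
                     signal_slab = c(2, 6), seed = 21)
  c1 <- simulate_cohort(2, sp)
  c2 <- simulate_cohort(2, sp)
  for (i in seq_along(c1$volumes))
    expect_identical(c1$volumes[[i]]$data, c2$volumes[[i]]$data)
  expect_equal(table(c1$manifest$label), table(c2$manifest$label))
})
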