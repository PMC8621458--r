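test_that("effect specification validates names, slopes and planting cells", {
  expect_error(effect_spec(target_features = "banana", slopes = 1),
               "plantable features")
  expect_error(effect_spec(target_features = "ratio_alpha_alpha_C3", slopes = 1),
               "plantable features")
  expect_error(effect_spec(target_features = c("np_alpha_C3", "ratio_alpha_beta_C3"),
                           slopes = c(1, 1)),
               "distinct")
  expect_error(effect_spec(target_features = "np_alpha_C3", slopes = c(1, 2)),
               "same length")
  expect_error(effect_spec(noise_sd = -1))
})

test_that("a noiseless planted feature correlates perfectly with FAS", {
  coh <- generate_cohort(8, effect_spec(target_features = "ratio_beta_theta_C3",
                                        slopes = -20, noise_sd = 0), seed = 31)
  ## extracted straight from the signals, full AO; stimulus-locked deflections
  ## add a sub-percent broadband perturbation to AO powers, hence the loose
  ## truth tolerance here (exact recovery is checked with deflections off)
  f <- suppressMessages(cohort_features(coh, durations = 240))
  r <- cor(f$ratio_beta_theta_C3, f$fas)
  expect_gt(abs(r), 0.999)
  expect_lt(r, 0)                                # slope < 0 propagates as r < 0
  expect_equal(f$ratio_beta_theta_C3, coh$truth$ratio_beta_theta_C3,
               tolerance = 0.01)
  ## with deflections disabled the planted ratio is recovered to float precision
  coh0 <- generate_cohort(4, effect_spec(target_features = "ratio_beta_theta_C3",
                                         slopes = -20, noise_sd = 0), seed = 31,
                          profile_defaults = list(p300_amplitude_uv = 0))
  f0 <- suppressMessages(cohort_features(coh0, durations = 240))
  expect_equal(f0$ratio_beta_theta_C3, coh0$truth$ratio_beta_theta_C3,
               tolerance = 1e-12)
})

test_that("planted noise level reproduces the correlation of a direct bivariate simulation", {
  ## direct oracle: simulate (feature, FAS) pairs from the same planting
  ## equations without any signal synthesis
  slope <- -20; noise_sd <- 5.5; n <- 50
  direct_r <- withr::with_seed(99, {
    mean(replicate(200, {
      fas <- sample(c(19, 27, 37), n, replace = TRUE, prob = c(3, 8, 6) / 17) +
        round(rnorm(n, 0, 2.5))
      f <- 1.5 + (fas - mean(fas) + rnorm(n, 0, noise_sd)) / slope
      cor(f, fas)
    }))
  })
  coh <- generate_cohort(n, effect_spec(target_features = "ratio_beta_theta_C3",
                                        slopes = slope, noise_sd = noise_sd),
                         seed = 77)
  feats <- suppressMessages(cohort_features(coh, durations = 240))
  observed_r <- cor(feats$ratio_beta_theta_C3, feats$fas)
  expect_equal(observed_r, direct_r, tolerance = 0.1)
})

test_that("cohort generation is seed-deterministic and records ground truth", {
  eff <- effect_spec(noise_sd = 1)
  c1 <- generate_cohort(4, eff, seed = 3)
  c2 <- generate_cohort(4, eff, seed = 3)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$bundles[[2]]$eeg, c2$bundles[[2]]$eeg)
  expect_equal(nrow(c1$truth), 4)
  expect_true(all(c1$effect$target_features %in% names(c1$truth)))
  expect_true(all(c1$truth$fas_total >= 10 & c1$truth$fas_total <= 50))
  c3 <- generate_cohort(4, eff, seed = 4)
  expect_false(identical(c1$bundles[[1]]$eeg, c3$bundles[[1]]$eeg))
})

test_that("class mix allocation follows the study proportions", {
  classes <- neurofas:::allocate_classes(17, c(no_fatigue = 3, substantial = 8,
                                               extreme = 6))
  expect_equal(table(classes)[["no_fatigue"]], 3)
  expect_equal(table(classes)[["substantial"]], 8)
  expect_equal(table(classes)[["extreme"]], 6)
  expect_equal(length(neurofas:::allocate_classes(14, c(no_fatigue = 3,
                                                        substantial = 8,
                                                        extreme = 6))), 14)
})
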