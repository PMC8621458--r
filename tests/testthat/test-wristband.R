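test_that("PPG tones land in their printed bands", {
  rate <- 64; t <- (0:(rate * 120 - 1)) / rate
  lf_tone <- ppg_spectra(sin(2 * pi * 0.1 * t), rate)
  expect_true(all(lf_tone$lf >= 100 * lf_tone$hf))
  expect_equal(lf_tone$tp, lf_tone$lf + lf_tone$hf + lf_tone$vlf, tolerance = 1e-9)
  expect_gt(min(lf_tone$lf / lf_tone$tp), 0.99)      # TP is essentially LF

  hf_tone <- ppg_spectra(sin(2 * pi * 0.25 * t), rate)
  expect_true(all(hf_tone$hf > 10 * hf_tone$lf))

  two <- ppg_spectra(sin(2 * pi * 0.1 * t) + sin(2 * pi * 0.25 * t), rate)
  ## equal-amplitude tones: the averaged LF/HF balance is within 10% even
  ## though the 0.25 Hz tone sits between bins (per-window leakage scatter)
  expect_lt(abs(mean(two$lf / two$hf) - 1), 0.1)
  expect_true(all(abs(two$lf / two$hf - 1) < 0.35))
  expect_error(ppg_spectra(sin(t[1:100]), rate), "shorter")
})

test_that("windowing follows the 30 s / 1 s sliding design", {
  rate <- 64; t <- (0:(rate * 240 - 1)) / rate
  sp <- ppg_spectra(sin(2 * pi * 0.1 * t), rate)
  expect_equal(nrow(sp), 240 - 30 + 1)
  expect_equal(sp$window_start_s, seq(0, 210))
})

test_that("LFNU matches the closed-form definition", {
  sp <- tibble::tibble(window_start_s = 0, vlf = 0, lf = 3, hf = 1, tp = 4)
  expect_equal(lfnu(sp), 0.75)
  ## all non-VLF power in LF reaches the upper bound
  sp2 <- tibble::tibble(window_start_s = 0, vlf = 0.5, lf = 2, hf = 0, tp = 2.5)
  expect_equal(lfnu(sp2), 1)
  ## formula oracle on random spectra
  withr::with_seed(6, {
    n <- 50
    sp3 <- tibble::tibble(window_start_s = seq_len(n),
                          vlf = rexp(n), lf = rexp(n), hf = rexp(n))
    sp3$tp <- sp3$vlf + sp3$lf + sp3$hf
    expect_equal(lfnu(sp3), sp3$lf / (sp3$tp - sp3$vlf), tolerance = 1e-12)
    expect_true(all(lfnu(sp3) >= 0 & lfnu(sp3) <= 1))
  })
  bad <- tibble::tibble(window_start_s = 0, vlf = 2, lf = 1, hf = 0, tp = 2)
  expect_error(lfnu(bad), "positive")
})

test_that("the wristband feature vector has ten stable entries", {
  b <- fixture_bundle()
  f <- e4_feature_vector(b)
  expect_identical(names(f), c("vlf", "lf", "hf", "tp", "lf_hf", "lfnu",
                               "ibi", "hr", "eda", "st"))
  expect_false(attr(f, "incomplete"))
  ## slow-stream features are plain means over the truncated AO task
  ao <- bundle_segment(b, "AO")
  expect_equal(f$eda, mean(ao$wristband$EDA$values), tolerance = 1e-12)
  expect_equal(f$hr, mean(ao$wristband$HR$values), tolerance = 1e-12)
  expect_equal(f$ibi, mean(ao$wristband$IBI$values), tolerance = 1e-12)
  ## a constant EDA stream returns exactly its level
  b2 <- b
  b2$wristband$EDA$values <- rep(2, length(b$wristband$EDA$values))
  expect_equal(e4_feature_vector(b2)$eda, 2)
})

test_that("a stationary PPG spectrum normalizes to zero against eyes-open", {
  b <- fixture_bundle()
  rate <- b$wristband$BVP$rate
  t <- (seq_along(b$wristband$BVP$values) - 1) / rate
  b$wristband$BVP$values <- sin(2 * pi * 0.1 * t)    # identical in EO and AO
  f <- e4_feature_vector(b)
  expect_equal(f$lf, 0, tolerance = 1e-9)
  expect_equal(f$tp, 0, tolerance = 1e-9)
})

test_that("the LF/HF feature reflects the planted amplitude ratio", {
  prof <- subject_profile(hrv_lf_amp = 2, hrv_hf_amp = 1, bvp_noise_sd = 0.01)
  b <- synthesize_recording(prof, generate_stimulus_schedule(seed = 3), seed = 3)
  f <- e4_feature_vector(b)
  expect_equal(f$lf_hf, 4, tolerance = 0.15 * 4)     # power scales as amplitude^2
  ## cross-check against the per-window identity
  sp <- ppg_spectra(bundle_segment(b, "AO")$wristband$BVP$values, 64)
  expect_equal(f$lf_hf, mean(sp$lf / sp$hf), tolerance = 1e-12)
})
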