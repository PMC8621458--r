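test_that("a single tone concentrates its power in the containing band", {
  fs <- 250; t <- (0:(fs * 20 - 1)) / fs
  seg <- fake_segment(sin(2 * pi * 10 * t), fs)
  bp <- band_power_series(seg)
  m <- tapply(bp$power, bp$band, mean)
  expect_true(all(m[["alpha"]] >= 100 * m[setdiff(names(m), "alpha")]))
  ## power scales with amplitude squared
  seg2 <- fake_segment(2 * sin(2 * pi * 10 * t), fs)
  bp2 <- band_power_series(seg2)
  expect_equal(mean(bp2$power[bp2$band == "alpha"]) /
                 mean(bp$power[bp$band == "alpha"]), 4, tolerance = 0.01)
})

test_that("white-noise band power is proportional to the band's bin count", {
  fs <- 250
  x <- withr::with_seed(11, rnorm(fs * 1000))
  bp <- band_power_series(fake_segment(x, fs))
  m <- tapply(bp$power, bp$band, mean)
  bins <- vapply(nf_bands(), function(b) sum(seq_len(125) >= b[1] & seq_len(125) <= b[2]),
                 numeric(1))
  per_bin <- m[names(bins)] / bins
  expect_lt(max(per_bin) / min(per_bin) - 1, 0.05)   # flat spectrum, MC tolerance
})

test_that("shared band edges follow the configured convention", {
  fs <- 250; t <- (0:(fs * 10 - 1)) / fs
  seg <- fake_segment(sin(2 * pi * 4 * t), fs)     # tone exactly at the 4 Hz edge
  bp_in <- band_power_series(seg)
  m_in <- tapply(bp_in$power, bp_in$band, mean)
  expect_gt(m_in[["delta"]], 0.4)                   # counted in both bands
  expect_gt(m_in[["theta"]], 0.4)
  bp_ho <- band_power_series(seg, edge = "half_open")
  m_ho <- tapply(bp_ho$power, bp_ho$band, mean)
  expect_gt(m_ho[["theta"]], 0.4)                   # 4 Hz belongs to theta only
  expect_lt(m_ho[["delta"]], 1e-6)
  expect_error(band_power_series(seg, bands = list(nothing = c(0.1, 0.2))),
               "no FFT bins")
})

test_that("eyes-open normalization matches the elementwise formula", {
  withr::with_seed(3, {
    ao_vals <- array(rexp(20 * 2 * 5) + 0.1, c(20, 2, 5))
    eo_vals <- array(rexp(5 * 2 * 5) + 0.1, c(5, 2, 5))
  })
  ao <- fake_bandpower(ao_vals, channels = c("C3", "O1"))
  eo <- fake_bandpower(eo_vals, channels = c("C3", "O1"))
  np <- normalize_power(ao, eo)
  ## independent oracle: direct (a - m) / m
  for (chn in c("C3", "O1")) for (bd in names(nf_bands())) {
    a <- ao$power[ao$channel == chn & ao$band == bd]
    m <- mean(eo$power[eo$channel == chn & eo$band == bd])
    expect_equal(np$np[np$channel == chn & np$band == bd], (a - m) / m,
                 tolerance = 1e-12)
  }
  expect_true(all(np$np >= -1))
})

test_that("normalization identity and scale-invariance hold", {
  vals <- array(2, c(3, 1, 5))
  ao <- fake_bandpower(vals); eo <- fake_bandpower(vals)
  np <- normalize_power(ao, eo)
  expect_true(all(np$np == 0))                       # AO equals the EO mean
  ao2 <- ao; ao2$power <- 2 * ao$power
  expect_true(all(normalize_power(ao2, eo)$np == 1)) # AO = 2 x EO mean
  ## multiplying both segments by a constant changes nothing
  ao3 <- ao; ao3$power <- 7 * ao$power
  eo3 <- eo; eo3$power <- 7 * eo$power
  expect_equal(normalize_power(ao3, eo3)$np, np$np, tolerance = 1e-12)
  eo0 <- eo; eo0$power <- 0
  expect_error(normalize_power(ao, eo0), "zero eyes-open")
})

test_that("the ratio set is complete, reciprocal and gain-invariant", {
  fs <- 250
  x <- withr::with_seed(4, rnorm(fs * 10))
  bp <- band_power_series(fake_segment(x, fs))
  rat <- power_ratios(bp)
  expect_equal(length(unique(rat$ratio)), 20)
  expect_equal(length(ratio_feature_names()), 160)   # 20 ratios x 8 channels
  ## reciprocal identity per window
  th_al <- rat$value[rat$ratio == "ratio_theta_alpha"]
  al_th <- rat$value[rat$ratio == "ratio_alpha_theta"]
  expect_equal(th_al * al_th, rep(1, length(th_al)), tolerance = 1e-12)
  ## channel gain cancels in every ratio
  bp_scaled <- band_power_series(fake_segment(3 * x, fs))
  rat2 <- power_ratios(bp_scaled)
  expect_equal(rat2$value, rat$value, tolerance = 1e-9)
  ## equal power in all bands gives all-1 ratios
  eq <- fake_bandpower(array(5, c(2, 1, 5)))
  expect_true(all(power_ratios(eq)$value == 1))
  z <- fake_bandpower(array(0, c(1, 1, 5)))
  expect_error(power_ratios(z), "positive")
})

test_that("the spectral feature vector is 200 named prefix means", {
  b <- fixture_bundle()
  ao <- band_power_series(bundle_segment(b, "AO"))
  eo <- band_power_series(bundle_segment(b, "EO"))
  np <- normalize_power(ao, eo)
  rat <- power_ratios(ao)
  f <- spectral_feature_vector(np, rat, 240)
  expect_equal(ncol(f), 200)
  expect_identical(names(f), c(np_feature_names(), ratio_feature_names()))
  ## truncation means over exactly the first 15 windows
  f15 <- spectral_feature_vector(np, rat, 15)
  oracle <- mean(np$np[np$channel == "C3" & np$band == "alpha" & np$window <= 15])
  expect_equal(f15$np_alpha_C3, oracle, tolerance = 1e-12)
  ## constant series average to the constant
  cst <- fake_bandpower(array(4, c(10, 1, 5)))
  npc <- normalize_power(cst, cst)
  expect_true(all(unlist(spectral_feature_vector(npc, power_ratios(cst), 10)[
    paste0("np_", names(nf_bands()), "_C3")]) == 0))
  expect_error(spectral_feature_vector(np, rat, 0.5), "at least 1 s")
  expect_error(spectral_feature_vector(np, rat, 500), "exceeds")
})
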