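test_that("the rare-stimulus average uses all 24 epochs on the 250-sample grid", {
  erp <- build_erp(fixture_bundle())
  expect_equal(attr(erp, "n_epochs"), 24)
  one <- erp[erp$channel == "C3", ]
  expect_equal(nrow(one), 250)
  expect_equal(diff(one$time_ms)[1], 4)
  expect_equal(range(one$time_ms), c(-196, 800))
})

test_that("identical epochs average to the (filtered) epoch waveform", {
  ## no background noise: every rare epoch is an identical copy of the bump
  prof <- subject_profile(band_amplitude = matrix(1e-12, 5, 8),
                          p300_amplitude_uv = 6, p300_latency_ms = 320)
  sched <- generate_stimulus_schedule(seed = 2)
  b <- synthesize_recording(prof, sched, seed = 2)
  erp <- build_erp(b)
  ## oracle: one isolated bump through the same zero-phase 0.1-10 Hz filter
  fs <- 250
  t <- (0:74999) / fs
  x <- 6 * exp(-((t - 150.32)^2) / (2 * 0.04^2))   # peak 320 ms after onset
  y <- neurofas:::butter_band_filtfilt(x, 0.1, 10, 4, fs)
  rel <- seq(-49, 200)
  oracle <- y[150 * fs + rel + 1]
  got <- erp$amplitude_uv[erp$channel == "FP2"]
  expect_equal(got, oracle, tolerance = 0.05)
  pk <- detect_p300(erp)
  expect_equal(unique(pk$latency_ms), 320)
})

test_that("a planted peak is localized to one sample at high SNR, per channel", {
  pk <- detect_p300(build_erp(fixture_quiet_bundle()))
  expect_true(all(abs(pk$latency_ms - 300) <= 4))
  expect_true(all(abs(pk$amplitude_uv - 8) / 8 <= 0.1))
})

test_that("peak detection is a windowed argmax with earliest-tie breaking", {
  tms <- seq(-196, 800, by = 4)
  gauss <- 6 * exp(-((tms - 320)^2) / (2 * 40^2))
  erp <- tibble::tibble(channel = "C3", time_ms = tms, amplitude_uv = gauss)
  pk <- detect_p300(erp)
  expect_equal(pk$amplitude_uv, 6)
  expect_equal(pk$latency_ms, 320)

  ## monotone decreasing waveform peaks at the window edge
  dec <- tibble::tibble(channel = "C3", time_ms = tms, amplitude_uv = -tms)
  expect_warning(pk2 <- detect_p300(dec), "not positive")
  expect_equal(pk2$latency_ms, 200)

  ## exhaustive-scan oracle on random waveforms
  withr::with_seed(5, {
    for (i in 1:25) {
      amp <- rnorm(length(tms))
      e <- tibble::tibble(channel = "C3", time_ms = tms, amplitude_uv = amp)
      pk3 <- suppressWarnings(detect_p300(e))
      inwin <- which(tms >= 200 & tms <= 500)
      best <- inwin[which.max(amp[inwin])]
      expect_equal(pk3$amplitude_uv, amp[best])
      expect_equal(pk3$latency_ms, tms[best])
    }
  })

  ## exact tie: earliest time wins
  flat <- tibble::tibble(channel = "C3", time_ms = tms,
                         amplitude_uv = rep(1, length(tms)))
  expect_equal(detect_p300(flat)$latency_ms, 200)
})

test_that("latency is invariant to adding a constant to the waveform", {
  erp <- build_erp(fixture_quiet_bundle())
  shifted <- erp
  shifted$amplitude_uv <- shifted$amplitude_uv + 5
  expect_equal(detect_p300(shifted)$latency_ms, detect_p300(erp)$latency_ms)
  expect_equal(detect_p300(shifted)$amplitude_uv,
               detect_p300(erp)$amplitude_uv + 5)
})

test_that("averaging more stimulus-free epochs shrinks the detected amplitude", {
  prof <- subject_profile(band_amplitude = default_band_amplitude() * 0.3,
                          p300_amplitude_uv = 0)
  means <- vapply(1:4, function(s) {
    b <- synthesize_recording(prof, generate_stimulus_schedule(seed = s), seed = s)
    amp24 <- mean(suppressWarnings(detect_p300(build_erp(b, "nonfrequent")))$amplitude_uv)
    amp96 <- mean(suppressWarnings(detect_p300(build_erp(b, "frequent")))$amplitude_uv)
    c(amp24, amp96)
  }, numeric(2))
  expect_lt(mean(means[2, ]), mean(means[1, ]))   # 96 epochs < 24 epochs
})

test_that("the 16 P300 features carry stable names and degrade to NA", {
  f <- p300_features(fixture_quiet_bundle())
  expect_identical(names(f), c(paste0("p300_amp_", nf_channels()),
                               paste0("p300_lat_", nf_channels())))
  expect_equal(ncol(f), 16)
  ## a truncation with no rare stimuli yields NA features, not an error
  b <- fixture_bundle()
  first_nf <- min(b$markers$onset_sample[b$markers$label == "nonfrequent"]) -
    b$segments$AO[1]
  short <- max(1, floor(first_nf / 250) - 1)
  f2 <- p300_features(b, duration_s = short)
  expect_true(all(is.na(unlist(f2))))
})

test_that("grand averages combine subjects with the sample-sd standard error", {
  e1 <- build_erp(fixture_quiet_bundle())
  ga1 <- grand_average(list(e1, e1))
  expect_equal(ga1$mean_uv, e1$amplitude_uv)
  expect_true(all(ga1$se_uv == 0))

  e2 <- e1; e2$amplitude_uv <- -e1$amplitude_uv
  ga2 <- grand_average(list(e1, e2))
  expect_true(all(abs(ga2$mean_uv) < 1e-12))

  ## direct-formula oracle on random waveforms
  withr::with_seed(7, {
    erps <- lapply(1:5, function(i) {
      e <- e1; e$amplitude_uv <- rnorm(nrow(e1)); e
    })
    ga <- grand_average(erps)
    amps <- sapply(erps, function(e) e$amplitude_uv)
    expect_equal(ga$mean_uv, rowMeans(amps), tolerance = 1e-12)
    expect_equal(ga$se_uv, apply(amps, 1, sd) / sqrt(5), tolerance = 1e-12)
  })

  bad <- e1[e1$channel != "O1", ]
  expect_error(grand_average(list(e1, bad)), "same channel")
})
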