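## Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

## default-profile bundle: band noise + 6 uV P300 at 300 ms, full wristband
fixture_bundle <- function() {
  memo("bundle", synthesize_recording(
    subject_profile(fas_total = 30),
    generate_stimulus_schedule(seed = 42), seed = 42))
}

## high-SNR bundle for per-channel ERP checks: quiet background, 8 uV bump
fixture_quiet_bundle <- function() {
  memo("quiet_bundle", synthesize_recording(
    subject_profile(fas_total = 30,
                    band_amplitude = default_band_amplitude() * 0.05,
                    p300_amplitude_uv = 8, p300_latency_ms = 300),
    generate_stimulus_schedule(seed = 42), seed = 43))
}

## single-channel segment view around a given signal (for spectral oracles)
fake_segment <- function(x, fs = 250, channels = "C3") {
  eeg <- matrix(x, ncol = length(channels))
  colnames(eeg) <- channels
  list(name = "AO", eeg = eeg, fs = fs, duration_s = nrow(eeg) / fs,
       markers = NULL, wristband = list())
}

## feature table with an exact planted linear effect plus noise columns,
## one duration; no signal synthesis (for fast model/evaluation tests)
make_features <- function(n = 14, seed = 1, noise_cols = 20) {
  withr::with_seed(seed, {
    fas <- c(sample(14:21, 3, TRUE), sample(22:35, 6, TRUE), sample(36:44, 5, TRUE))
    f <- tibble::tibble(subject_id = sprintf("S%02d", 1:n), duration_s = 240,
                        fas = fas, incomplete = FALSE)
    f$ratio_beta_theta_C3 <- (100 - fas) / 20
    f$ratio_alpha_theta_O2 <- (80 - fas) / 15
    f$np_alpha_O1 <- fas / 50
    for (j in seq_len(noise_cols)) f[[paste0("np_delta_ch", j)]] <- rnorm(n)
    for (nm in e4_feature_names()) f[[nm]] <- rnorm(n)
    f
  })
}

## hand-built band-power tibble (windows x channels x bands)
fake_bandpower <- function(values, channels = "C3", bands = names(nf_bands())) {
  n_win <- dim(values)[1]
  tibble::tibble(
    window = rep(seq_len(n_win), each = length(bands) * length(channels)),
    channel = rep(rep(channels, each = length(bands)), n_win),
    band = rep(bands, length(channels) * n_win),
    power = as.vector(aperm(values, c(3, 2, 1)))
  )
}
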