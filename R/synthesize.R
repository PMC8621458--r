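#' Synthesize one 5-minute recording from a subject profile
#'
#' Emits a complete [recording_bundle()] for the standard session layout
#' (30 s EC, 30 s EO, 240 s AO). The EEG of each channel is band-structured
#' noise: within every 1-s block, each frequency band is a random-phase sum of
#' harmonics on the 1 Hz analysis grid whose total power is fixed exactly to
#' the profile's band amplitude (RMS) for that segment, so band powers
#' estimated by the 1-s FFT stage recover the planted amplitudes without
#' sampling error. The delta and theta bands are synthesized on the interiors
#' of their printed ranges (1-3 Hz and 5-7 Hz) because the shared 4 Hz edge
#' bin is counted in both bands at analysis time.
#'
#' On top of the band noise, every non-frequent stimulus adds a positive
#' Gaussian deflection on all channels (height `p300_amplitude_uv`, peak
#' `p300_latency_ms` after onset, width `p300_sigma_ms`) — the planted P300.
#' The wristband streams are: BVP as the sum of the two planted HRV sinusoids
#' plus white noise, and EDA/TEMP/HR/IBI as tonic levels with a small drift
#' and noise. Streams listed in `profile$missing_streams` are absent.
#'
#' @param profile A [subject_profile()].
#' @param schedule A marker table from [generate_stimulus_schedule()]; must
#'   fit inside the AO segment.
#' @param seed Integer seed; identical inputs reproduce the bundle
#'   bit-for-bit.
#' @return A [recording_bundle()] with the profile's FAS questionnaire
#'   attached.
#' @export
synthesize_recording <- function(profile, schedule = generate_stimulus_schedule(seed = seed),
                                 seed = 1) {
  stopifnot(inherits(profile, "subject_profile"))
  fs <- nf_eeg_fs()
  segs <- nf_segments()
  n_total <- segs$AO[2]
  n_blocks <- n_total / fs                       # 300 one-second blocks
  ao_blocks <- (segs$AO[1] / fs + 1):n_blocks
  ch <- nf_channels()

  if (nrow(schedule) == 0) abort("`schedule` must contain at least one stimulus.")
  if (min(schedule$onset_sample) < segs$AO[1] ||
      max(schedule$onset_sample) >= segs$AO[2]) {
    abort("`schedule` does not fit inside the AO segment.")
  }
  if (profile$p300_latency_ms <= 0 || profile$p300_latency_ms >= 800) {
    abort("planted P300 latency lies outside the (0, 800) ms epoch window.")
  }

  ## generation bins per band: printed edges, except the shared 4 Hz bin
  gen_bins <- list(delta = 1:3, theta = 5:7, alpha = 8:12, beta = 13:29, gamma = 30:50)
  bins <- unlist(gen_bins, use.names = FALSE)
  band_of <- rep(names(gen_bins), lengths(gen_bins))
  tt <- (0:(fs - 1)) / fs
  Cmat <- cos(2 * pi * outer(tt, bins))          # fs x n_bins
  Smat <- sin(2 * pi * outer(tt, bins))

  withr::with_seed(seed, {
    eeg <- matrix(0, n_total, length(ch), dimnames = list(NULL, ch))
    for (c_i in seq_along(ch)) {
      raw <- matrix(sqrt(rexp(length(bins) * n_blocks)), length(bins), n_blocks)
      phi <- matrix(runif(length(bins) * n_blocks, 0, 2 * pi), length(bins), n_blocks)
      M <- raw
      for (b in names(gen_bins)) {
        rows <- which(band_of == b)
        amp <- rep(profile$band_amplitude[b, ch[c_i]], n_blocks)
        amp[ao_blocks] <- profile$ao_band_amplitude[b, ch[c_i]]
        norm <- sqrt(colSums(raw[rows, , drop = FALSE]^2) / 2)
        scale <- ifelse(norm > 0, amp / norm, 0)
        M[rows, ] <- raw[rows, , drop = FALSE] * rep(scale, each = length(rows))
      }
      X <- Cmat %*% (M * cos(phi)) - Smat %*% (M * sin(phi))
      eeg[, c_i] <- as.vector(X)
    }

    ## planted P300 deflections on every channel after non-frequent onsets
    if (profile$p300_amplitude_uv > 0) {
      bump_t <- 0:(0.8 * fs)                    # samples 0..800 ms post-onset
      bump <- profile$p300_amplitude_uv *
        exp(-((bump_t * 1000 / fs - profile$p300_latency_ms)^2) /
              (2 * profile$p300_sigma_ms^2))
      for (o in schedule$onset_sample[schedule$label == "nonfrequent"]) {
        idx <- o + bump_t + 1L
        keep <- idx <= n_total
        eeg[idx[keep], ] <- eeg[idx[keep], ] + bump[keep]
      }
    }

    rates <- nf_stream_rates()
    dur_s <- n_total / fs
    t_bvp <- (0:(dur_s * rates["BVP"] - 1)) / rates["BVP"]
    streams <- list(
      BVP = list(rate = rates[["BVP"]], values =
        profile$hrv_lf_amp * sin(2 * pi * profile$hrv_lf_hz * t_bvp) +
        profile$hrv_hf_amp * sin(2 * pi * profile$hrv_hf_hz * t_bvp + pi / 3) +
        rnorm(length(t_bvp), 0, profile$bvp_noise_sd)),
      EDA = list(rate = rates[["EDA"]], values = {
        n <- dur_s * rates[["EDA"]]
        profile$eda_level + 0.1 * seq_len(n) / n + rnorm(n, 0, 0.01)
      }),
      TEMP = list(rate = rates[["TEMP"]], values = {
        n <- dur_s * rates[["TEMP"]]
        profile$st_level - 0.2 * seq_len(n) / n + rnorm(n, 0, 0.01)
      }),
      HR = list(rate = rates[["HR"]], values =
        profile$hr_bpm + rnorm(dur_s, 0, 0.5)),
      IBI = list(rate = rates[["IBI"]], values =
        60 / profile$hr_bpm + rnorm(dur_s, 0, 0.005))
    )
    streams <- streams[setdiff(names(streams), profile$missing_streams)]

    fas <- score_fas(fas_items_from_total(profile$fas_total))

    recording_bundle(
      eeg = eeg,
      markers = schedule[, c("onset_sample", "label")],
      wristband = streams,
      fas = fas,
      subject_id = profile$subject_id
    )
  })
}

## split a FAS total (10..50) into ten 1-5 items summing to it
fas_items_from_total <- function(total) {
  base <- total %/% 10L
  rem <- total - base * 10L
  items <- rep(base, 10L)
  if (rem > 0) {
    bump <- sample.int(10L, rem)
    items[bump] <- items[bump] + 1L
  }
  as.integer(items)
}
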