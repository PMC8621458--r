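#' Sliding-window PPG band powers
#'
#' Computes, on 30-s windows advanced by 1 s, the FFT periodogram power of
#' the wrist PPG (blood-volume-pulse) signal summed over the cardiovascular
#' bands: VLF (below 0.04 Hz), LF (0.04-0.15 Hz), HF (0.15-0.4 Hz) and TP
#' (0-0.4 Hz). Each window is mean-removed and the DC bin dropped. The
#' printed VLF upper edge (0.03 Hz) falls below the 1/30 Hz bin resolution,
#' so VLF collects every non-DC bin under the LF lower edge.
#'
#' @param values Numeric PPG samples.
#' @param rate Sampling rate, Hz.
#' @param window_s Window length, seconds (the segment must be at least this
#'   long).
#' @param step_s Window step, seconds.
#' @return An `nf_ppg` tibble: `window_start_s`, `vlf`, `lf`, `hf`, `tp`.
#' @export
ppg_spectra <- function(values, rate, window_s = 30, step_s = 1) {
  n_w <- floor(window_s * rate)
  if (length(values) < n_w) {
    abort(sprintf("PPG segment (%.1f s) is shorter than the %g s analysis window.",
                  length(values) / rate, window_s))
  }
  starts_s <- seq(0, length(values) / rate - window_s, by = step_s)
  bands <- nf_ppg_bands()
  half <- floor(n_w / 2)
  freqs <- seq_len(half) * rate / n_w
  idx <- outer(seq_len(n_w), floor(starts_s * rate), "+")
  X <- matrix(values[idx], n_w, length(starts_s))
  X <- sweep(X, 2, colMeans(X))                 # mean-removed, DC dropped
  FT <- stats::mvfft(X)
  P <- 2 * Mod(FT[1L + seq_len(half), , drop = FALSE])^2 / n_w^2
  if (n_w %% 2L == 0L) P[half, ] <- P[half, ] / 2
  band_sum <- function(lo, hi, strict_hi = FALSE) {
    s <- if (strict_hi) freqs < hi - 1e-9 else freqs >= lo - 1e-9 & freqs <= hi + 1e-9
    if (!strict_hi) s <- s & freqs >= lo - 1e-9
    colSums(P[s, , drop = FALSE])
  }
  out <- tibble(
    window_start_s = starts_s,
    vlf = band_sum(0, bands$lf[1], strict_hi = TRUE),
    lf  = band_sum(bands$lf[1], bands$lf[2]),
    hf  = band_sum(bands$hf[1], bands$hf[2]),
    tp  = band_sum(0, bands$tp[2])
  )
  structure(out, class = c("nf_ppg", class(out)), window_s = window_s)
}

#' LF in normalized units
#'
#' `LFNU(t) = LF(t) / (TP(t) - VLF(t))` per window; lies in \[0, 1\] whenever
#' the band powers are consistent (TP >= LF + VLF).
#'
#' @param spectra An `nf_ppg` tibble from [ppg_spectra()].
#' @return Numeric vector of per-window values.
#' @export
lfnu <- function(spectra) {
  den <- spectra$tp - spectra$vlf
  if (any(den <= 0)) abort("TP - VLF must be positive in every window.")
  spectra$lf / den
}

#' Wristband feature vector for one subject
#'
#' The ten wristband features over the AO task, averaged across sliding
#' windows up to `duration_s`: the four PPG band powers normalized against
#' the subject's eyes-open baseline (same construction as the EEG
#' normalization), the LF/HF ratio and LFNU computed prior to normalization,
#' and the plain means of IBI, HR, EDA and skin temperature. Stable names:
#' `vlf, lf, hf, tp, lf_hf, lfnu, ibi, hr, eda, st`.
#'
#' For truncations shorter than the 30-s spectral window, the window length
#' shrinks to the truncation (applied to both AO and EO so the normalization
#' compares like with like); a band left with no bins at the coarser
#' resolution yields `NA` for its normalized feature.
#'
#' @param bundle A [recording_bundle()].
#' @param duration_s Seconds of AO data to use (default: all 240).
#' @return One-row tibble of 10 named features, with attribute `incomplete`
#'   set when any required stream (BVP, EDA, TEMP, HR, IBI) is missing — the
#'   features are then all `NA` and the subject should be excluded.
#' @export
e4_feature_vector <- function(bundle, duration_s = 240) {
  nm <- e4_feature_names()
  required <- names(nf_stream_rates())
  missing <- setdiff(required, names(bundle$wristband))
  if (length(missing)) {
    warn(sprintf("subject %s lacks stream(s) %s; flagged incomplete.",
                 bundle$subject_id, paste(missing, collapse = ", ")))
    out <- as_tibble(setNames(as.list(rep(NA_real_, length(nm))), nm))
    return(structure(out, incomplete = TRUE))
  }
  ao <- bundle_segment(bundle, "AO", max_duration_s = duration_s)
  eo <- bundle_segment(bundle, "EO")
  win_s <- min(30, duration_s)

  sp_ao <- ppg_spectra(ao$wristband$BVP$values, ao$wristband$BVP$rate, window_s = win_s)
  sp_eo <- ppg_spectra(eo$wristband$BVP$values, eo$wristband$BVP$rate, window_s = win_s)

  norm_band <- function(band) {
    m_eo <- mean(sp_eo[[band]])
    if (m_eo <= 0) return(NA_real_)
    mean((sp_ao[[band]] - m_eo) / m_eo)
  }
  if (any(sp_ao$hf <= 0)) abort("HF power must be positive to form LF/HF.")
  vals <- c(
    vlf = norm_band("vlf"), lf = norm_band("lf"),
    hf = norm_band("hf"), tp = norm_band("tp"),
    lf_hf = mean(sp_ao$lf / sp_ao$hf),
    lfnu = mean(lfnu(sp_ao)),
    ibi = mean(ao$wristband$IBI$values),
    hr = mean(ao$wristband$HR$values),
    eda = mean(ao$wristband$EDA$values),
    st = mean(ao$wristband$TEMP$values)
  )
  structure(as_tibble(as.list(vals[nm])), incomplete = FALSE)
}
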