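#' Filtering specification for the EEG chain
#'
#' The acquisition chain applies a 60 Hz notch (powerline) followed by a
#' 0.1-100 Hz 4th-order Butterworth bandpass, both zero-phase
#' (forward-backward). "4th order" is the designed order before the
#' forward-backward pass (effective order 8). The bandpass is realized as an
#' order-4 high-pass cascaded with an order-4 low-pass, which is numerically
#' robust at the very low 0.1 Hz edge; the notch is a biquad with Q = 30.
#'
#' @param notch_hz Notch center frequency, Hz (`NULL` disables it).
#' @param bandpass Length-2 numeric, band edges in Hz.
#' @param order Butterworth design order.
#' @param notch_q Notch quality factor.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(notch_hz = 60, bandpass = c(0.1, 100), order = 4,
                        notch_q = 30) {
  nyq <- nf_eeg_fs() / 2
  if (length(bandpass) != 2 || bandpass[1] <= 0 || bandpass[1] >= bandpass[2]) {
    abort("`bandpass` must be increasing positive edges (low, high).")
  }
  if (bandpass[2] >= nyq) {
    abort(sprintf("bandpass high edge must be below the Nyquist frequency (%g Hz).", nyq))
  }
  structure(list(notch_hz = notch_hz, bandpass = bandpass, order = order,
                 notch_q = notch_q, zero_phase = TRUE),
            class = "filter_spec")
}

## zero-phase biquad notch (RBJ design)
notch_filtfilt <- function(x, f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::filtfilt(b / a[1], a / a[1], x)
}

## zero-phase Butterworth band limitation as HP + LP cascade
butter_band_filtfilt <- function(x, low, high, order, fs) {
  nyq <- fs / 2
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Apply the zero-phase filtering chain to a bundle's EEG
#'
#' Notch first, then bandpass, each forward-backward so the output has zero
#' phase lag; signal length and markers are unchanged.
#'
#' @param bundle A [recording_bundle()].
#' @param spec A [filter_spec()].
#' @return The bundle with filtered EEG.
#' @export
apply_filters <- function(bundle, spec = filter_spec()) {
  stopifnot(inherits(bundle, "recording_bundle"), inherits(spec, "filter_spec"))
  fs <- bundle$fs
  eeg <- bundle$eeg
  for (j in seq_len(ncol(eeg))) {
    x <- eeg[, j]
    if (!is.null(spec$notch_hz)) {
      x <- notch_filtfilt(x, spec$notch_hz, fs, spec$notch_q)
    }
    eeg[, j] <- butter_band_filtfilt(x, spec$bandpass[1], spec$bandpass[2],
                                     spec$order, fs)
  }
  bundle$eeg <- eeg
  bundle
}

#' Artifact subspace reconstruction configuration
#'
#' ASR removes high-variance transients by comparing, window by window, the
#' signal's variance along the principal directions of a clean calibration
#' segment against `kappa` times the calibration standard deviation in each
#' direction; directions that exceed the threshold are projected out and the
#' window is reconstructed from the retained subspace. `kappa = 15` keeps the
#' cleaning conservative: genuine EEG passes through numerically unchanged
#' and only large muscle/movement transients are attenuated.
#'
#' @param kappa Threshold multiplier (> 0).
#' @param window_s Sliding-window length, seconds (50% overlap, Hann
#'   overlap-add).
#' @param calibration_segment `"EC"` or `"EO"`; which baseline segment
#'   calibrates the clean subspace when cleaning a whole bundle.
#' @return An `asr_config` list.
#' @export
asr_config <- function(kappa = 15, window_s = 0.5, calibration_segment = "EC") {
  stopifnot_scalar_number(kappa, "kappa")
  if (kappa <= 0) abort("`kappa` must be > 0.")
  if (window_s <= 0) abort("`window_s` must be > 0.")
  if (!calibration_segment %in% c("EC", "EO")) {
    abort("`calibration_segment` must be 'EC' or 'EO'.")
  }
  structure(list(kappa = kappa, window_s = window_s,
                 calibration_segment = calibration_segment),
            class = "asr_config")
}

#' Clean a multichannel signal by artifact subspace reconstruction
#'
#' The signal is processed in Hann-tapered windows of `cfg$window_s` seconds
#' with 50% overlap. In each window, the principal components of the window
#' itself are computed and each component's variance is compared against
#' `(kappa x calibration standard deviation along that same direction)^2`,
#' the calibration variance being the quadratic form of the calibration
#' covariance; components over threshold are zeroed and the window rebuilt
#' from the retained subspace, then overlap-added. Windows with no component
#' over threshold are reproduced exactly (up to float round-off), so clean
#' data passes through unchanged and a second pass over already-cleaned data
#' changes nothing beyond round-off.
#'
#' @param eeg Numeric matrix, samples x channels.
#' @param calib Calibration matrix (same channels), at least 10 s long.
#' @param cfg An [asr_config()].
#' @param fs Sampling rate, Hz.
#' @return Cleaned matrix, same dimensions.
#' @export
asr_clean <- function(eeg, calib, cfg = asr_config(), fs = nf_eeg_fs()) {
  stopifnot(is.matrix(eeg), is.matrix(calib), ncol(eeg) == ncol(calib))
  if (nrow(calib) < 10 * fs) abort("calibration segment must be at least 10 s long.")
  n_w <- round(cfg$window_s * fs)
  if (n_w %% 2L == 1L) n_w <- n_w + 1L
  if (nrow(calib) < n_w) abort("calibration shorter than the sliding window.")
  hop <- n_w %/% 2L
  n <- nrow(eeg)

  Ccal <- stats::cov(calib)
  kappa2 <- cfg$kappa^2

  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n_w - 1)) / n_w)   # periodic Hann
  out <- matrix(0, n, ncol(eeg))
  wsum <- numeric(n)
  starts <- seq(1L, n, by = hop)
  for (s in starts) {
    idx <- s:min(s + n_w - 1L, n)
    F0 <- eeg[idx, , drop = FALSE]
    ## principal components of this window; threshold each against kappa^2
    ## times the calibration variance along the same direction
    eig <- eigen(crossprod(F0) / length(idx), symmetric = TRUE)
    U <- eig$vectors
    calib_var <- colSums(U * (Ccal %*% U))      # u_j' C u_j per component
    drop_dir <- eig$values > kappa2 * calib_var
    F1 <- if (any(drop_dir)) {
      Y <- F0 %*% U
      Y[, drop_dir] <- 0
      Y %*% t(U)
    } else F0
    wloc <- w[seq_along(idx)]
    out[idx, ] <- out[idx, ] + F1 * wloc
    wsum[idx] <- wsum[idx] + wloc
  }
  zero <- wsum < 1e-12
  wsum[zero] <- 1
  out <- out / wsum
  out[zero, ] <- eeg[zero, , drop = FALSE]
  colnames(out) <- colnames(eeg)
  out
}

#' Preprocess a bundle: filtering chain plus ASR cleaning
#'
#' Applies [apply_filters()] and then [asr_clean()] to the whole EEG, with the
#' clean subspace calibrated on the (filtered) segment named in
#' `asr$calibration_segment`.
#'
#' @param bundle A [recording_bundle()].
#' @param filters A [filter_spec()] (`NULL` skips filtering).
#' @param asr An [asr_config()] (`NULL` skips cleaning).
#' @return The preprocessed bundle.
#' @export
preprocess_bundle <- function(bundle, filters = filter_spec(), asr = asr_config()) {
  if (!is.null(filters)) bundle <- apply_filters(bundle, filters)
  if (!is.null(asr)) {
    calib <- bundle_segment(bundle, asr$calibration_segment)$eeg
    bundle$eeg <- asr_clean(bundle$eeg, calib, asr, fs = bundle$fs)
  }
  bundle
}
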