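#' Build stimulus-locked average waveforms (ERPs)
#'
#' Epochs the EEG around every stimulus onset carrying `target_label`,
#' bandpass-filters 0.1-10 Hz (zero phase, applied to the continuous signal
#' before epoching so short epochs carry no filter edge effects), averages
#' pointwise per channel, and baseline-corrects. Epochs span -200 ms to
#' +800 ms around onset on the 4 ms sample grid (250 samples, onset at the
#' 50th sample), matching the oddball analysis protocol: with the standard
#' 120-stimulus schedule the non-frequent average uses 24 epochs.
#'
#' The default baseline is the mean (filtered) eyes-open amplitude per
#' channel; `baseline = "prestim"` instead subtracts each channel's mean over
#' the -200-0 ms pre-stimulus interval (the conventional ERP baseline).
#'
#' @param bundle A [recording_bundle()].
#' @param target_label `"nonfrequent"` (default) or `"frequent"`.
#' @param duration_s Optional AO truncation: only onsets whose full epoch fits
#'   inside the first `duration_s` seconds of the AO task are used.
#' @param baseline `"EO"` or `"prestim"`.
#' @param erp_band Length-2 numeric, the epoch filter band in Hz.
#' @param .filt Precomputed epoch-filtered EEG matrix (internal; lets callers
#'   that epoch the same recording at several truncations filter once).
#' @return An `nf_erp` tibble with columns `channel`, `time_ms`,
#'   `amplitude_uv`, and attributes `n_epochs`, `n_dropped`, `baseline`.
#' @export
build_erp <- function(bundle, target_label = "nonfrequent", duration_s = NULL,
                      baseline = c("EO", "prestim"), erp_band = c(0.1, 10),
                      .filt = NULL) {
  baseline <- match.arg(baseline)
  fs <- bundle$fs
  pre <- round(0.2 * fs) - 1L     # 49 samples before onset: times -196..0 ms
  post <- round(0.8 * fs)         # 200 samples after onset
  times_ms <- seq(-pre, post) * 1000 / fs

  filt <- .filt %||% erp_band_filter(bundle$eeg, erp_band, fs)

  ao <- bundle$segments$AO
  onsets <- bundle$markers$onset_sample[bundle$markers$label == target_label]
  if (!is.null(duration_s)) {
    lim <- ao[1] + floor(duration_s * fs)
    onsets <- onsets[onsets + post < lim]
  }
  usable <- onsets[onsets - pre >= 0 & onsets + post < nrow(filt)]
  n_dropped <- length(onsets) - length(usable)
  if (n_dropped > 0) {
    inform(sprintf("build_erp: dropped %d epoch(s) exceeding the recording bounds.", n_dropped))
  }
  if (length(usable) == 0) {
    abort(sprintf("no usable '%s' epochs%s.", target_label,
                  if (is.null(duration_s)) "" else sprintf(" within %g s", duration_s)))
  }

  rel <- seq(-pre, post)
  n_ch <- ncol(filt)
  erp <- matrix(0, length(rel), n_ch)
  for (o in usable) erp <- erp + filt[o + rel + 1L, , drop = FALSE]
  erp <- erp / length(usable)

  base <- if (baseline == "EO") {
    eo <- bundle$segments$EO
    colMeans(filt[(eo[1] + 1L):eo[2], , drop = FALSE])
  } else {
    colMeans(erp[times_ms <= 0, , drop = FALSE])
  }
  erp <- sweep(erp, 2, base)

  out <- tibble(
    channel = rep(nf_channels(), each = length(rel)),
    time_ms = rep(times_ms, n_ch),
    amplitude_uv = as.vector(erp)
  )
  structure(out, class = c("nf_erp", class(out)),
            n_epochs = length(usable), n_dropped = n_dropped,
            baseline = baseline)
}

#' Detect the P300 peak of an averaged waveform
#'
#' The P300 amplitude is the highest point of the averaged waveform in the
#' immediate post-stimulus 200-500 ms window, and the latency the time from
#' stimulus onset to that peak; ties break to the earliest time. The window
#' maximum is returned even when it is not positive, with a warning, since a
#' fatigued or noisy average need not show a positive deflection.
#'
#' @param erp An `nf_erp` tibble (one or more channels), or any data frame
#'   with `channel`, `time_ms`, `amplitude_uv`.
#' @param window Length-2 numeric, the search window in ms.
#' @return Tibble with one row per channel: `channel`, `amplitude_uv`,
#'   `latency_ms`.
#' @export
detect_p300 <- function(erp, window = c(200, 500)) {
  win <- dplyr::filter(erp, .data$time_ms >= window[1], .data$time_ms <= window[2])
  if (nrow(win) == 0) abort("the waveform does not cover the 200-500 ms window.")
  out <- win |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      peak_idx = {
        if (all(is.na(.data$amplitude_uv))) abort("all-NA amplitudes in the P300 window.")
        which.max(.data$amplitude_uv)   # first maximum = earliest tie
      },
      amplitude_uv = .data$amplitude_uv[.data$peak_idx[1]],
      latency_ms = .data$time_ms[.data$peak_idx[1]],
      .groups = "drop"
    ) |>
    dplyr::select(-"peak_idx") |>
    dplyr::arrange(match(.data$channel, nf_channels()))
  if (any(out$amplitude_uv <= 0)) {
    warn("detected P300 peak is not positive on at least one channel.")
  }
  out
}

## zero-phase 0.1-10 Hz epoch filter applied to the continuous recording
erp_band_filter <- function(eeg, erp_band = c(0.1, 10), fs = nf_eeg_fs()) {
  apply(eeg, 2, butter_band_filtfilt,
        low = erp_band[1], high = erp_band[2], order = 4, fs = fs)
}

#' Per-subject P300 feature vector
#'
#' Runs [build_erp()] on the non-frequent stimuli and [detect_p300()], and
#' returns the 16 P300 features (amplitude and latency per channel) as a
#' named one-row tibble (`p300_amp_<ch>`, `p300_lat_<ch>`). If no usable
#' epoch exists at the requested truncation the features are all `NA`.
#'
#' @inheritParams build_erp
#' @return One-row tibble of 16 named features.
#' @export
p300_features <- function(bundle, duration_s = NULL, baseline = "EO",
                          .filt = NULL) {
  nm <- p300_feature_names()
  peaks <- tryCatch({
    erp <- suppressMessages(
      build_erp(bundle, "nonfrequent", duration_s = duration_s,
                baseline = baseline, .filt = .filt))
    suppressWarnings(detect_p300(erp))
  }, error = function(e) NULL)
  if (is.null(peaks)) {
    return(as_tibble(setNames(as.list(rep(NA_real_, 16L)), nm)))
  }
  vals <- c(setNames(peaks$amplitude_uv, paste0("p300_amp_", peaks$channel)),
            setNames(peaks$latency_ms, paste0("p300_lat_", peaks$channel)))
  as_tibble(as.list(vals[nm]))
}

#' Grand average of per-subject ERPs
#'
#' Pointwise mean and standard error across subjects, per channel and time
#' point. All inputs must share the same channel set and time axis.
#'
#' @param erps List of `nf_erp` tibbles (one per subject).
#' @return Tibble with `channel`, `time_ms`, `mean_uv`, `se_uv`, `n`.
#' @export
grand_average <- function(erps) {
  if (length(erps) < 1) abort("`erps` must contain at least one waveform.")
  ref <- erps[[1]][, c("channel", "time_ms")]
  for (e in erps) {
    if (!isTRUE(all.equal(e[, c("channel", "time_ms")], ref, tolerance = 1e-9))) {
      abort("all ERPs must share the same channel and time axes.")
    }
  }
  amp <- vapply(erps, function(e) e$amplitude_uv, numeric(nrow(ref)))
  amp <- matrix(amp, nrow = nrow(ref))
  n <- length(erps)
  tibble(
    channel = ref$channel,
    time_ms = ref$time_ms,
    mean_uv = rowMeans(amp),
    se_uv = if (n > 1) apply(amp, 1, sd) / sqrt(n) else 0,
    n = n
  )
}
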