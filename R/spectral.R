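#' Per-window EEG band powers
#'
#' Splits a segment view into non-overlapping 1-s windows aligned to the
#' segment start and computes, per window and channel, the FFT periodogram
#' power summed over the bins of each frequency band (1 Hz resolution at
#' 250 Hz). Band edges are inclusive on both sides exactly as printed, so the
#' shared 4 Hz bin contributes to both delta and theta; `edge = "half_open"`
#' instead assigns each edge bin to the lower band only
#' (`low <= f < high`, last band inclusive).
#'
#' @param segment A segment view from [bundle_segment()] (>= 1 s of EEG).
#' @param bands Named list of band edges in Hz (default [nf_bands()]); every
#'   band must contain at least one FFT bin.
#' @param window_s Window length, seconds.
#' @param edge Band-edge convention.
#' @return An `nf_bandpower` tibble, one row per (window, channel, band):
#'   `window` (1-based), `channel`, `band`, `power` (microvolt^2).
#' @export
band_power_series <- function(segment, bands = nf_bands(), window_s = 1,
                              edge = c("inclusive", "half_open")) {
  edge <- match.arg(edge)
  fs <- segment$fs
  n_w <- floor(window_s * fs)
  n_win <- floor(nrow(segment$eeg) / n_w)
  if (n_win < 1) abort("segment must contain at least one full window.")
  half <- floor(n_w / 2)
  freqs <- seq_len(half) * fs / n_w
  sel <- band_bins(freqs, bands, edge)

  ch <- colnames(segment$eeg)
  ## power array: bands x channels x windows, filled per channel via one FFT
  ## over the stacked non-overlapping windows
  pow <- array(NA_real_, c(length(bands), length(ch), n_win))
  for (j in seq_along(ch)) {
    X <- matrix(segment$eeg[seq_len(n_win * n_w), j], n_w, n_win)
    FT <- stats::mvfft(X)
    P <- 2 * Mod(FT[1L + seq_len(half), , drop = FALSE])^2 / n_w^2
    if (n_w %% 2L == 0L) P[half, ] <- P[half, ] / 2
    for (bi in seq_along(bands)) {
      pow[bi, j, ] <- colSums(P[sel[[bi]], , drop = FALSE])
    }
  }
  out <- tibble(
    window = rep(seq_len(n_win), each = length(bands) * length(ch)),
    channel = rep(rep(ch, each = length(bands)), n_win),
    band = rep(names(bands), length(ch) * n_win),
    power = as.vector(pow)
  )
  structure(out, class = c("nf_bandpower", class(out)),
            window_s = window_s, fs = fs)
}

band_bins <- function(freqs, bands, edge) {
  sel <- lapply(seq_along(bands), function(bi) {
    lo <- bands[[bi]][1]; hi <- bands[[bi]][2]
    s <- if (edge == "inclusive") {
      freqs >= lo - 1e-9 & freqs <= hi + 1e-9
    } else if (bi == length(bands)) {
      freqs >= lo - 1e-9 & freqs <= hi + 1e-9
    } else {
      freqs >= lo - 1e-9 & freqs < hi - 1e-9
    }
    which(s)
  })
  names(sel) <- names(bands)
  empty <- lengths(sel) == 0
  if (any(empty)) {
    abort(sprintf("band(s) with no FFT bins at this resolution: %s",
                  paste(names(bands)[empty], collapse = ", ")))
  }
  sel
}

#' Eyes-open-normalized band powers
#'
#' Normalizes every AO window's band power against the subject's own mean
#' eyes-open power in the same channel and band:
#' `NP(t) = (AO(t) - mean_EO) / mean_EO`. The normalization is strictly
#' per-subject; values are >= -1 because powers are non-negative, and 0 when
#' an AO window equals the eyes-open mean.
#'
#' @param ao,eo `nf_bandpower` tibbles for the AO and EO segments of the same
#'   subject (matching channels and bands).
#' @return An `nf_normpower` tibble: `window`, `channel`, `band`, `np`.
#' @export
normalize_power <- function(ao, eo) {
  eo_mean <- eo |>
    dplyr::group_by(.data$channel, .data$band) |>
    dplyr::summarise(eo_mean = mean(.data$power), .groups = "drop")
  if (!setequal(paste(eo_mean$channel, eo_mean$band),
                unique(paste(ao$channel, ao$band)))) {
    abort("AO and EO band powers must cover the same channels and bands.")
  }
  bad <- eo_mean[eo_mean$eo_mean <= 0, ]
  if (nrow(bad)) {
    abort(sprintf("zero eyes-open mean power for: %s",
                  paste(paste0(bad$channel, "/", bad$band), collapse = ", ")))
  }
  out <- ao |>
    dplyr::inner_join(eo_mean, by = c("channel", "band")) |>
    dplyr::mutate(np = (.data$power - .data$eo_mean) / .data$eo_mean) |>
    dplyr::select("window", "channel", "band", "np")
  structure(out, class = c("nf_normpower", class(out)))
}

#' Per-window band-power ratios
#'
#' All 20 ordered pairs of distinct bands per channel, computed window by
#' window from the powers prior to normalization: `ratio_<b1>_<b2>` is
#' `power(b1) / power(b2)`. Scale-invariant to channel gain.
#'
#' @param ao An `nf_bandpower` tibble.
#' @return Tibble: `window`, `channel`, `ratio` (name), `value`.
#' @export
power_ratios <- function(ao) {
  wide <- tidyr::pivot_wider(ao, names_from = "band", values_from = "power")
  bandcols <- as.matrix(wide[, names(nf_bands())])
  if (any(bandcols <= 0)) abort("all band powers must be positive to form ratios.")
  p <- ratio_pairs()
  res <- lapply(seq_len(nrow(p)), function(k) {
    tibble(
      window = wide$window,
      channel = wide$channel,
      ratio = paste0("ratio_", p$b1[k], "_", p$b2[k]),
      value = bandcols[, p$b1[k]] / bandcols[, p$b2[k]]
    )
  })
  dplyr::bind_rows(res)
}

#' Spectral feature vector for one subject
#'
#' Averages the normalized powers and the per-window ratios over the first
#' `floor(duration_s)` AO windows, yielding the 200 spectral features with
#' stable names `np_<band>_<ch>` (40) and `ratio_<b1>_<b2>_<ch>` (160).
#'
#' @param ao_np An `nf_normpower` tibble from [normalize_power()].
#' @param ao_ratios A ratio tibble from [power_ratios()].
#' @param duration_s Seconds of AO data to average over (>= 1).
#' @return One-row tibble of 200 named features.
#' @export
spectral_feature_vector <- function(ao_np, ao_ratios, duration_s) {
  if (duration_s < 1) abort("`duration_s` must be at least 1 s.")
  n_keep <- floor(duration_s)
  if (n_keep > max(ao_np$window)) {
    abort(sprintf("duration %g s exceeds the %d available windows.",
                  duration_s, max(ao_np$window)))
  }
  np <- ao_np |>
    dplyr::filter(.data$window <= n_keep) |>
    dplyr::group_by(.data$channel, .data$band) |>
    dplyr::summarise(value = mean(.data$np), .groups = "drop") |>
    dplyr::mutate(feature = paste0("np_", .data$band, "_", .data$channel))
  rat <- ao_ratios |>
    dplyr::filter(.data$window <= n_keep) |>
    dplyr::group_by(.data$channel, .data$ratio) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(feature = paste0(.data$ratio, "_", .data$channel))
  vals <- setNames(c(np$value, rat$value), c(np$feature, rat$feature))
  nm <- c(np_feature_names(), ratio_feature_names())
  as_tibble(as.list(setNames(vals[nm], nm)))
}
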