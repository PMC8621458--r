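## Session layout, channel montage and feature-name universe shared across modules.

#' Recording constants
#'
#' The acquisition protocol fixes a 5-minute session: 30 s eyes closed (EC),
#' 30 s eyes open (EO) and a 4-minute auditory oddball (AO) task. EEG is
#' sampled at 250 Hz on eight dry electrodes of the 10-20 system referenced to
#' the earlobes; the wristband streams run at their native rates (BVP 64 Hz,
#' EDA/TEMP 4 Hz, HR/IBI 1 Hz).
#'
#' @return `nf_channels()` returns the ordered channel names; `nf_bands()` the
#'   named list of EEG band edges in Hz; `nf_segments()` the 0-based half-open
#'   sample intervals of the three session segments at 250 Hz;
#'   `nf_stream_rates()` the wristband sampling rates in Hz.
#' @export
nf_channels <- function() c("FP2", "FP1", "C4", "C3", "P8", "P7", "O1", "O2")

#' @rdname nf_channels
#' @export
nf_bands <- function() {
  list(
    delta = c(1, 4),
    theta = c(4, 7),
    alpha = c(8, 12),
    beta  = c(13, 29),
    gamma = c(30, 50)
  )
}

#' @rdname nf_channels
#' @export
nf_segments <- function() {
  fs <- nf_eeg_fs()
  list(
    EC = c(0L, 30L * fs),
    EO = c(30L * fs, 60L * fs),
    AO = c(60L * fs, 300L * fs)
  )
}

#' @rdname nf_channels
#' @export
nf_stream_rates <- function() c(BVP = 64, EDA = 4, TEMP = 4, HR = 1, IBI = 1)

#' @rdname nf_channels
#' @export
nf_eeg_fs <- function() 250L

## PPG (cardiovascular) analysis bands, Hz. The printed VLF upper edge
## (0.03 Hz) sits below the 1/30 Hz resolution of a 30-s window, so VLF
## membership is "below the LF lower edge" once DC is dropped.
nf_ppg_bands <- function() {
  list(vlf = c(0, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4), tp = c(0, 0.4))
}

## --- feature-name universe ------------------------------------------------

p300_feature_names <- function() {
  ch <- nf_channels()
  c(paste0("p300_amp_", ch), paste0("p300_lat_", ch))
}

np_feature_names <- function() {
  as.vector(outer(names(nf_bands()), nf_channels(),
                  function(b, ch) paste0("np_", b, "_", ch)))
}

ratio_pairs <- function() {
  b <- names(nf_bands())
  pairs <- expand.grid(b2 = b, b1 = b, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$b1 != pairs$b2, c("b1", "b2")]
  pairs[order(match(pairs$b1, b), match(pairs$b2, b)), ]
}

ratio_feature_names <- function() {
  p <- ratio_pairs()
  as.vector(vapply(nf_channels(), function(ch) {
    paste0("ratio_", p$b1, "_", p$b2, "_", ch)
  }, character(20)))
}

e4_feature_names <- function() {
  c("vlf", "lf", "hf", "tp", "lf_hf", "lfnu", "ibi", "hr", "eda", "st")
}

#' Names of the full feature set
#'
#' The pipeline produces 226 named features per subject: 16 P300 features
#' (amplitude and latency per channel), 40 eyes-open-normalized band powers,
#' 160 band-power ratios, and 10 wristband features.
#'
#' @return Character vector of length 226, in stable order.
#' @export
nf_feature_names <- function() {
  c(p300_feature_names(), np_feature_names(), ratio_feature_names(),
    e4_feature_names())
}

## Wristband features used by the E4 model variant (the six most correlated
## wristband features reported by the study).
e4_model_features <- function() c("st", "lf", "tp", "hf", "lfnu", "lf_hf")
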