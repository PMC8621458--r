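#' Recording bundle: one subject's synchronized session
#'
#' A `recording_bundle` holds everything recorded in one 5-minute session:
#' the EEG matrix (samples x 8 channels, microvolts, 250 Hz), the stimulus
#' marker table of the oddball task, the EC/EO/AO segment boundaries, the
#' wristband streams at their native rates, and (optionally) the subject's
#' fatigue questionnaire result.
#'
#' @param eeg Numeric matrix, samples x channels, with column names equal to
#'   [nf_channels()]. Units: microvolts.
#' @param markers Tibble with columns `onset_sample` (0-based index at 250 Hz,
#'   strictly increasing, inside the AO segment) and `label`
#'   (`"frequent"`/`"nonfrequent"`).
#' @param wristband Named list of streams; each element is
#'   `list(rate = <Hz>, values = <numeric>)`. Streams may be absent (an
#'   incomplete subject).
#' @param fas A `fas_result` (see [score_fas()]) or `NULL`.
#' @param segments List of 0-based half-open `[start, end)` sample intervals
#'   named `EC`, `EO`, `AO`; defaults to the standard 30/30/240-s layout.
#' @param subject_id Character id.
#' @param start_time POSIXct/numeric UTC session start (stored in exports).
#'
#' @return An object of class `recording_bundle`.
#' @export
recording_bundle <- function(eeg, markers, wristband = list(), fas = NULL,
                             segments = nf_segments(),
                             subject_id = "S01",
                             start_time = 0) {
  if (!is.matrix(eeg) || !is.numeric(eeg)) abort("`eeg` must be a numeric matrix.")
  if (is.null(colnames(eeg)) || !identical(colnames(eeg), nf_channels())) {
    abort(paste0("`eeg` must have columns ", paste(nf_channels(), collapse = ", "), "."))
  }
  n <- nrow(eeg)
  segs <- segments[c("EC", "EO", "AO")]
  if (anyNA(names(segs)) || any(vapply(segs, is.null, logical(1)))) {
    abort("`segments` must name EC, EO and AO.")
  }
  bounds <- do.call(rbind, segs)
  if (any(bounds[, 1] >= bounds[, 2])) abort("segment intervals must be non-empty.")
  if (!(bounds["EC", 2] <= bounds["EO", 1] && bounds["EO", 2] <= bounds["AO", 1])) {
    abort("segments must be ordered EC < EO < AO and disjoint.")
  }
  if (bounds["AO", 2] > n) abort("segments exceed the EEG length.")
  markers <- as_tibble(markers)
  if (!all(c("onset_sample", "label") %in% names(markers))) {
    abort("`markers` needs columns onset_sample, label.")
  }
  if (is.unsorted(markers$onset_sample, strictly = TRUE)) {
    abort("marker onsets must be strictly increasing.")
  }
  if (!all(markers$label %in% c("frequent", "nonfrequent"))) {
    abort("marker labels must be 'frequent' or 'nonfrequent'.")
  }
  ao <- segs$AO
  if (nrow(markers) &&
      (min(markers$onset_sample) < ao[1] || max(markers$onset_sample) >= ao[2])) {
    abort("all marker onsets must lie inside the AO segment.")
  }
  for (nm in names(wristband)) {
    st <- wristband[[nm]]
    if (!is.list(st) || is.null(st$rate) || is.null(st$values) || st$rate <= 0) {
      abort(sprintf("wristband stream '%s' must be list(rate > 0, values).", nm))
    }
  }
  structure(
    list(eeg = eeg, markers = markers, segments = segs, wristband = wristband,
         fas = fas, subject_id = subject_id, start_time = start_time,
         fs = nf_eeg_fs()),
    class = "recording_bundle"
  )
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> subject %s: %d EEG samples x %d channels @ %d Hz\n",
              x$subject_id, nrow(x$eeg), ncol(x$eeg), x$fs))
  cat(sprintf("  markers: %d (%d nonfrequent); wristband: %s; FAS: %s\n",
              nrow(x$markers), sum(x$markers$label == "nonfrequent"),
              if (length(x$wristband)) paste(names(x$wristband), collapse = ",") else "none",
              if (is.null(x$fas)) "absent" else x$fas$total))
  invisible(x)
}

#' Extract a segment view of a bundle
#'
#' Returns the EEG (and, by time alignment, the wristband streams) of one of
#' the session segments, optionally truncated to its first `max_duration_s`
#' seconds. Truncation at duration T keeps exactly `floor(T * rate)` samples
#' of each signal at its own rate. For the AO segment, marker onsets are
#' re-expressed relative to the segment start and restricted to the truncated
#' span.
#'
#' @param bundle A [recording_bundle()].
#' @param name `"EC"`, `"EO"` or `"AO"`.
#' @param max_duration_s Optional truncation, seconds.
#' @return A list with `eeg` (samples x channels), `fs`, `duration_s`,
#'   `markers` (AO only; onsets relative to segment start, 0-based) and
#'   `wristband` (streams truncated at their own rates).
#' @export
bundle_segment <- function(bundle, name, max_duration_s = NULL) {
  if (!name %in% names(bundle$segments)) {
    abort(sprintf("unknown segment '%s' (expected EC, EO or AO).", name))
  }
  seg <- bundle$segments[[name]]
  fs <- bundle$fs
  seg_len_s <- (seg[2] - seg[1]) / fs
  dur <- max_duration_s %||% seg_len_s
  if (dur > seg_len_s + 1e-9) {
    abort(sprintf("max_duration_s = %s exceeds the %s segment (%s s).", dur, name, seg_len_s))
  }
  n_keep <- floor(dur * fs)
  idx <- seq.int(seg[1] + 1L, seg[1] + n_keep)
  seg_start_s <- seg[1] / fs
  wb <- lapply(bundle$wristband, function(st) {
    i0 <- floor(seg_start_s * st$rate)
    nk <- floor(dur * st$rate)
    list(rate = st$rate, values = st$values[seq.int(i0 + 1L, min(i0 + nk, length(st$values)))])
  })
  mk <- NULL
  if (name == "AO") {
    mk <- bundle$markers
    mk$onset_sample <- mk$onset_sample - seg[1]
    mk <- mk[mk$onset_sample < n_keep, , drop = FALSE]
  }
  list(name = name, eeg = bundle$eeg[idx, , drop = FALSE], fs = fs,
       duration_s = n_keep / fs, start_sample = seg[1], markers = mk,
       wristband = wb)
}
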