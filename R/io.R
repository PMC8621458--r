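#' Score the Fatigue Assessment Scale
#'
#' The FAS is a 10-item questionnaire, each item scored 1-5; the total
#' (10-50) is binned into three classes: no fatigue (total <= 21),
#' substantial fatigue (22-35) and extreme fatigue (>= 36). Reverse-scored
#' items (x -> 6 - x) are off by default and configurable: the standard FAS
#' reverses items 4 and 10, but scoring here defaults to the plain sum.
#'
#' @param items Integer vector of 10 item scores, each in 1..5.
#' @param reverse_items Integer indices of items to reverse-score.
#' @return A `fas_result`: list with `items`, `total` and `fatigue_class`.
#' @export
#' @examples
#' score_fas(rep(2, 10))$fatigue_class
score_fas <- function(items, reverse_items = integer(0)) {
  if (length(items) != 10L) abort("`items` must contain exactly 10 scores.")
  if (any(items != round(items)) || any(items < 1) || any(items > 5)) {
    abort("every FAS item must be an integer in 1..5.")
  }
  items <- as.integer(items)
  scored <- items
  scored[reverse_items] <- 6L - scored[reverse_items]
  total <- sum(scored)
  structure(list(items = items, reverse_items = as.integer(reverse_items),
                 total = total, fatigue_class = fas_class(total)),
            class = "fas_result")
}

#' Fatigue class from a FAS total
#'
#' `fas_class()` bins integer questionnaire totals by the printed ranges
#' (<= 21 / 22-35 / >= 36). `fas_class_pred()` bins real-valued model
#' predictions with the midpoint extension of those integer bins
#' (cut points 21.5 and 35.5).
#'
#' @param total Numeric vector of FAS totals (or predictions).
#' @return Character vector in
#'   `c("no_fatigue", "substantial", "extreme")`.
#' @export
fas_class <- function(total) {
  ifelse(total <= 21, "no_fatigue", ifelse(total <= 35, "substantial", "extreme"))
}

#' @rdname fas_class
#' @export
fas_class_pred <- function(total) {
  ifelse(total < 21.5, "no_fatigue", ifelse(total < 35.5, "substantial", "extreme"))
}

#' Write / read a recording bundle as plain-text files
#'
#' The on-disk layout mirrors the two device export dialects: `eeg.csv` with
#' a channel-name header and one row per sample (microvolts, 250 Hz);
#' `markers.csv` with 0-based `onset_sample` and `label`; one file per
#' wristband stream (`BVP.csv`, `EDA.csv`, `TEMP.csv`, `HR.csv`, `IBI.csv`)
#' in the wristband-export convention — first line the UTC start timestamp,
#' second line the sampling rate in Hz, then one value per line; optional
#' `fas.csv` with the questionnaire items; and `manifest.json` holding the
#' subject id and segment boundaries. A write-then-read round trip reproduces
#' every signal to float precision and all metadata exactly.
#'
#' @param bundle A [recording_bundle()].
#' @param path Directory to write into (created if missing).
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()` returns
#'   the reconstructed [recording_bundle()]. A missing EEG file is fatal; a
#'   missing wristband stream file loads with that stream absent and a
#'   warning, so the subject can be flagged incomplete downstream.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "recording_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(bundle$eeg), file.path(path, "eeg.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$markers, file.path(path, "markers.csv"),
                   progress = FALSE)
  for (nm in names(bundle$wristband)) {
    st <- bundle$wristband[[nm]]
    writeLines(
      c(sprintf("%.6f", as.numeric(bundle$start_time)),
        sprintf("%.6f", st$rate),
        sprintf("%.17g", st$values)),
      file.path(path, paste0(nm, ".csv"))
    )
  }
  if (!is.null(bundle$fas)) {
    readr::write_csv(
      tibble(item = seq_len(10L), score = bundle$fas$items),
      file.path(path, "fas.csv"), progress = FALSE)
  }
  manifest <- list(
    subject_id = bundle$subject_id,
    start_time = as.numeric(bundle$start_time),
    eeg_rate_hz = bundle$fs,
    segments = lapply(bundle$segments, as.integer),
    reverse_items = if (is.null(bundle$fas)) integer(0) else bundle$fas$reverse_items
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  eeg_file <- file.path(path, "eeg.csv")
  if (!file.exists(eeg_file)) abort(sprintf("missing EEG file: %s", eeg_file))
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  eeg_df <- readr::read_csv(eeg_file, show_col_types = FALSE, progress = FALSE)
  eeg <- as.matrix(eeg_df)
  markers <- readr::read_csv(file.path(path, "markers.csv"),
                             col_types = "ic", progress = FALSE)
  wristband <- list()
  for (nm in names(nf_stream_rates())) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) {
      warn(sprintf("wristband stream %s missing in %s; loading without it.", nm, path))
      next
    }
    lines <- readLines(f)
    wristband[[nm]] <- list(rate = as.numeric(lines[2]),
                            values = as.numeric(lines[-(1:2)]))
  }
  fas <- NULL
  fas_file <- file.path(path, "fas.csv")
  if (file.exists(fas_file)) {
    fas_df <- readr::read_csv(fas_file, col_types = "ii", progress = FALSE)
    fas <- score_fas(fas_df$score,
                     reverse_items = unlist(manifest$reverse_items) %||% integer(0))
  }
  recording_bundle(
    eeg = eeg, markers = markers, wristband = wristband, fas = fas,
    segments = lapply(manifest$segments, as.integer),
    subject_id = manifest$subject_id,
    start_time = manifest$start_time
  )
}

#' Write / read a synthetic cohort
#'
#' One subdirectory per subject (see [write_bundle()]) plus a
#' `cohort_manifest.json` recording the seed, the effect specification and
#' the ground-truth table, so parameter-recovery checks can run against data
#' loaded from disk.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param path Directory.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort_bundles()`
#'   returns the named list of bundles.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$bundles)) {
    write_bundle(cohort$bundles[[id]], file.path(path, id))
  }
  manifest <- list(
    seed = cohort$seed,
    effect = list(
      target_features = cohort$effect$target_features,
      slopes = cohort$effect$slopes,
      noise_sd = cohort$effect$noise_sd,
      class_mix = as.list(cohort$effect$class_mix)
    ),
    truth = cohort$truth
  )
  jsonlite::write_json(manifest, file.path(path, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort_bundles <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "eeg.csv"))]
  bundles <- lapply(dirs, read_bundle)
  names(bundles) <- vapply(bundles, function(b) b$subject_id, character(1))
  bundles[order(names(bundles))]
}
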