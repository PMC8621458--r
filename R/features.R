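#' Extract the full 226-feature vector at one or more task durations
#'
#' Runs the three feature extractors on one bundle — P300 amplitude/latency
#' (16), eyes-open-normalized band powers (40), band-power ratios (160) and
#' wristband features (10) — once per requested AO truncation. Band powers
#' are computed once on the full AO task and averaged over window prefixes,
#' so the per-duration features share one spectral decomposition.
#'
#' Any preprocessing (filter chain, ASR) is applied beforehand via
#' [preprocess_bundle()]; extraction itself only applies the 0.1-10 Hz epoch
#' filter that defines the ERP stage.
#'
#' @param bundle A [recording_bundle()].
#' @param durations Numeric vector of AO durations in seconds
#'   (default `c(240, 120, 60, 30, 15)`).
#' @param baseline ERP baseline mode, see [build_erp()].
#' @return Tibble with one row per duration: `subject_id`, `duration_s`,
#'   `fas`, `incomplete`, then the 226 features in [nf_feature_names()]
#'   order. P300 features are `NA` at truncations with no usable non-frequent
#'   epoch; wristband features are `NA` when a stream is missing (and
#'   `incomplete` is `TRUE`).
#' @export
extract_features <- function(bundle, durations = c(240, 120, 60, 30, 15),
                             baseline = "EO") {
  ao <- bundle_segment(bundle, "AO")
  eo <- bundle_segment(bundle, "EO")
  bp_ao <- band_power_series(ao)
  bp_eo <- band_power_series(eo)
  np <- normalize_power(bp_ao, bp_eo)
  ratios <- power_ratios(bp_ao)
  erp_filt <- erp_band_filter(bundle$eeg, fs = bundle$fs)

  rows <- lapply(durations, function(d) {
    spec <- spectral_feature_vector(np, ratios, duration_s = d)
    p300 <- p300_features(bundle, duration_s = d, baseline = baseline,
                          .filt = erp_filt)
    e4 <- e4_feature_vector(bundle, duration_s = d)
    dplyr::bind_cols(
      tibble(subject_id = bundle$subject_id, duration_s = d,
             fas = if (is.null(bundle$fas)) NA_integer_ else bundle$fas$total,
             incomplete = isTRUE(attr(e4, "incomplete"))),
      p300, spec, e4
    )
  })
  dplyr::bind_rows(rows)
}

#' Extract features for every subject of a cohort
#'
#' Maps [extract_features()] over the bundles of a [generate_cohort()] result
#' (or any named list of bundles), optionally preprocessing each bundle
#' first.
#'
#' @param cohort A `synthetic_cohort` or a named list of
#'   [recording_bundle()]s.
#' @param durations AO truncations in seconds.
#' @param filters,asr Passed to [preprocess_bundle()] when `preprocess` is
#'   `TRUE`.
#' @param preprocess Apply the filter chain and ASR before extraction?
#'   Defaults to `FALSE`: synthetic recordings are clean by construction, and
#'   preprocessing belongs to runs on recorded data (see [run_pipeline()]).
#' @return Row-bound feature tibble, one row per (subject, duration).
#' @export
cohort_features <- function(cohort, durations = c(240, 120, 60, 30, 15),
                            preprocess = FALSE,
                            filters = filter_spec(), asr = asr_config()) {
  bundles <- if (inherits(cohort, "synthetic_cohort")) cohort$bundles else cohort
  purrr::map(bundles, function(b) {
    if (preprocess) b <- preprocess_bundle(b, filters, asr)
    extract_features(b, durations = durations)
  }) |>
    dplyr::bind_rows()
}
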