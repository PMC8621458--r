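#' Subject profile: ground truth for one synthetic recording
#'
#' A `subject_profile` fixes everything the synthesizer needs to emit one
#' session: per-band, per-channel EEG amplitudes (microvolt RMS) for the
#' baseline (EC/EO) and the oddball (AO) segments, the planted P300 peak
#' (latency and height of a Gaussian deflection time-locked to non-frequent
#' stimuli), the oscillatory content of the wrist PPG surrogate, tonic levels
#' of the slow streams, and the subject's FAS total.
#'
#' @param subject_id Character id.
#' @param fas_total Integer FAS total in 10..50.
#' @param band_amplitude 5 x 8 matrix (bands x channels, microvolt RMS) of
#'   baseline band amplitudes; rows named as [nf_bands()], columns as
#'   [nf_channels()]. Scalars are recycled.
#' @param ao_band_amplitude Same shape, amplitudes during the AO task
#'   (defaults to `band_amplitude`; differences are what the eyes-open
#'   normalization measures).
#' @param p300_latency_ms,p300_amplitude_uv,p300_sigma_ms Peak time after
#'   non-frequent stimulus onset (must lie in the 0–800 ms epoch window),
#'   peak height in microvolts (0 disables the deflection), and Gaussian
#'   width.
#' @param hrv_lf_hz,hrv_hf_hz Frequencies of the low- (0.04–0.15 Hz) and
#'   high-frequency (0.15–0.4 Hz) oscillations planted in the PPG surrogate.
#' @param hrv_lf_amp,hrv_hf_amp Their amplitudes (arbitrary BVP units).
#' @param bvp_noise_sd Additive white-noise level of the PPG surrogate.
#' @param eda_level,st_level,hr_bpm Tonic electrodermal level (microsiemens),
#'   skin temperature (deg C) and heart rate (beats/min).
#' @param missing_streams Character subset of
#'   `c("BVP","EDA","TEMP","HR","IBI")` to drop from the emitted bundle
#'   (emulates subjects excluded for missing data).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S01",
                            fas_total = 25L,
                            band_amplitude = default_band_amplitude(),
                            ao_band_amplitude = NULL,
                            p300_latency_ms = 300,
                            p300_amplitude_uv = 6,
                            p300_sigma_ms = 40,
                            hrv_lf_hz = 0.1, hrv_hf_hz = 0.25,
                            hrv_lf_amp = 1, hrv_hf_amp = 1,
                            bvp_noise_sd = 0.05,
                            eda_level = 2, st_level = 33, hr_bpm = 70,
                            missing_streams = character(0)) {
  stopifnot_scalar_number(fas_total, "fas_total", 10, 50)
  stopifnot_scalar_number(p300_amplitude_uv, "p300_amplitude_uv", min = 0)
  if (p300_latency_ms <= 0 || p300_latency_ms >= 800) {
    abort("`p300_latency_ms` must lie strictly inside the (0, 800) ms epoch window.")
  }
  if (hrv_lf_hz <= 0.04 || hrv_lf_hz >= 0.15) abort("`hrv_lf_hz` must be in (0.04, 0.15).")
  if (hrv_hf_hz <= 0.15 || hrv_hf_hz >= 0.4) abort("`hrv_hf_hz` must be in (0.15, 0.4).")
  band_amplitude <- as_band_matrix(band_amplitude, "band_amplitude")
  ao_band_amplitude <- if (is.null(ao_band_amplitude)) band_amplitude
                       else as_band_matrix(ao_band_amplitude, "ao_band_amplitude")
  for (nm in c("hrv_lf_amp", "hrv_hf_amp", "bvp_noise_sd", "eda_level", "hr_bpm")) {
    stopifnot_scalar_number(get(nm), nm, min = 0)
  }
  bad <- setdiff(missing_streams, names(nf_stream_rates()))
  if (length(bad)) abort(sprintf("unknown stream(s): %s", paste(bad, collapse = ", ")))
  structure(
    list(subject_id = subject_id, fas_total = as.integer(round(fas_total)),
         band_amplitude = band_amplitude, ao_band_amplitude = ao_band_amplitude,
         p300_latency_ms = p300_latency_ms, p300_amplitude_uv = p300_amplitude_uv,
         p300_sigma_ms = p300_sigma_ms,
         hrv_lf_hz = hrv_lf_hz, hrv_hf_hz = hrv_hf_hz,
         hrv_lf_amp = hrv_lf_amp, hrv_hf_amp = hrv_hf_amp,
         bvp_noise_sd = bvp_noise_sd,
         eda_level = eda_level, st_level = st_level, hr_bpm = hr_bpm,
         missing_streams = missing_streams),
    class = "subject_profile"
  )
}

as_band_matrix <- function(x, name) {
  bands <- names(nf_bands()); ch <- nf_channels()
  if (is.numeric(x) && length(x) == 1L) {
    x <- matrix(x, length(bands), length(ch))
  }
  if (!is.matrix(x) || !identical(dim(x), c(length(bands), length(ch)))) {
    abort(sprintf("`%s` must be a %d x %d bands-by-channels matrix or a scalar.",
                  name, length(bands), length(ch)))
  }
  if (any(x < 0)) abort(sprintf("`%s` amplitudes must be >= 0.", name))
  dimnames(x) <- list(bands, ch)
  x
}

#' @rdname subject_profile
#' @export
default_band_amplitude <- function() {
  ## resting-EEG-like microvolt RMS per band, identical across channels
  as_band_matrix(matrix(c(10, 6, 8, 4, 2), 5, 8), "band_amplitude")
}

#' Planted feature-fatigue effect specification
#'
#' Declares which pipeline features the synthetic cohort should carry a linear
#' dependence on, with which slopes (FAS units per feature unit) and how much
#' FAS-scale Gaussian noise around the plane. Plantable features are the
#' band-power ratios (`ratio_<b1>_<b2>_<ch>`) and the normalized band powers
#' (`np_<band>_<ch>`): the generator inverts the feature definition, choosing
#' AO band amplitudes whose extracted power ratio (or eyes-open-normalized
#' power) equals the planted value.
#'
#' @param target_features Character vector of plantable feature names.
#' @param slopes Numeric, same length: FAS units per feature unit.
#' @param noise_sd FAS-scale residual standard deviation (0 = exact plane).
#' @param style_sd With two or more targets, the FAS-scale standard deviation
#'   of per-subject variation in how the fatigue signature distributes across
#'   the target features. It is drawn in the null space of the slope vector,
#'   so the planted linear relation between FAS and the features is untouched
#'   (exact at `noise_sd = 0`) while the features decorrelate enough for the
#'   individual slopes to be identifiable.
#' @param class_mix Named counts of subjects per fatigue class used as mixing
#'   proportions; defaults to the 3/8/6 no/substantial/extreme mix of the
#'   study cohort.
#' @param feature_centers Optional named numeric of per-feature center values
#'   (defaults: 1.5 for ratios, 0.3 for normalized powers).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(target_features = c("ratio_beta_theta_C3",
                                            "ratio_alpha_theta_O2",
                                            "np_alpha_O1"),
                        slopes = c(-20, -15, 25),
                        noise_sd = 0,
                        style_sd = 1.5,
                        class_mix = c(no_fatigue = 3, substantial = 8, extreme = 6),
                        feature_centers = NULL) {
  if (length(slopes) != length(target_features)) {
    abort("`slopes` and `target_features` must have the same length.")
  }
  if (any(slopes == 0)) abort("planted slopes must be nonzero.")
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(style_sd, "style_sd", min = 0)
  if (!all(c("no_fatigue", "substantial", "extreme") %in% names(class_mix))) {
    abort("`class_mix` must name no_fatigue, substantial and extreme.")
  }
  parsed <- lapply(target_features, parse_plantable_feature)
  cells <- vapply(parsed, function(p) paste(p$planted_band, p$channel), character(1))
  if (anyDuplicated(cells)) {
    abort("target features must plant distinct (band, channel) cells.")
  }
  centers <- vapply(seq_along(parsed), function(j) {
    nm <- target_features[j]
    if (!is.null(feature_centers) && nm %in% names(feature_centers)) {
      feature_centers[[nm]]
    } else if (parsed[[j]]$type == "ratio") 1.5 else 0.3
  }, numeric(1))
  structure(
    list(target_features = target_features, slopes = slopes, noise_sd = noise_sd,
         style_sd = style_sd, class_mix = class_mix,
         centers = setNames(centers, target_features), parsed = parsed),
    class = "effect_spec"
  )
}

parse_plantable_feature <- function(name) {
  bands <- names(nf_bands()); ch <- nf_channels()
  valid <- paste0(
    "plantable features are 'ratio_<b1>_<b2>_<ch>' (b1 != b2) and ",
    "'np_<band>_<ch>' with bands {", paste(bands, collapse = ", "),
    "} and channels {", paste(ch, collapse = ", "), "}")
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) == 4 && parts[1] == "ratio" &&
      all(parts[2:3] %in% bands) && parts[2] != parts[3] && parts[4] %in% ch) {
    return(list(type = "ratio", b1 = parts[2], b2 = parts[3], channel = parts[4],
                planted_band = parts[2]))
  }
  if (length(parts) == 3 && parts[1] == "np" && parts[2] %in% bands && parts[3] %in% ch) {
    return(list(type = "np", band = parts[2], channel = parts[3],
                planted_band = parts[2]))
  }
  abort(sprintf("cannot plant feature '%s'; %s.", name, valid))
}

#' Generate a synthetic cohort with planted feature-fatigue effects
#'
#' Draws one [subject_profile()] per subject (FAS totals from the class mix,
#' band amplitudes jittered around [default_band_amplitude()]), plants the
#' effect declared in `effect`, and synthesizes every recording. Planting
#' inverts the feature definitions: for a target value f, a ratio target sets
#' the numerator band's AO amplitude to `sqrt(f)` times the denominator
#' band's, and a normalized-power target scales the band's AO amplitude by
#' `sqrt(1 + f)` relative to baseline. With `noise_sd = 0` the FAS totals lie
#' exactly on the planted plane of the extracted features.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effect An [effect_spec()].
#' @param seed Master integer seed; everything (class assignment, profiles,
#'   schedules, signals) derives from it deterministically.
#' @param profile_defaults Named list of [subject_profile()] arguments to
#'   override the drawn values (e.g. `list(p300_amplitude_uv = 0)` to disable
#'   stimulus-locked deflections in a spectral-recovery experiment).
#' @return A `synthetic_cohort`: list with `bundles`, `profiles`, `effect`,
#'   `seed` and a `truth` tibble (subject id, FAS total, fatigue class and the
#'   planted value of every target feature).
#' @export
generate_cohort <- function(n_subjects, effect = effect_spec(), seed = 1,
                            profile_defaults = list()) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  stopifnot(inherits(effect, "effect_spec"))
  classes <- allocate_classes(n_subjects, effect$class_mix)

  L <- length(effect$target_features)
  master <- derive_seed(seed, 0L)
  draws <- withr::with_seed(master, {
    fas <- vapply(classes, draw_fas_total, integer(1))
    fas_bar <- mean(fas)
    eta <- matrix(rnorm(n_subjects * L, 0, effect$noise_sd * sqrt(L)),
                  n_subjects, L)
    ## per-subject style variation, FAS units, orthogonal to the planted
    ## plane: its row means vanish so sum_j s_j * (style term of f_j) == 0
    zeta <- matrix(0, n_subjects, L)
    if (L > 1 && effect$style_sd > 0) {
      zeta <- matrix(rnorm(n_subjects * L, 0, effect$style_sd), n_subjects, L)
      zeta <- zeta - rowMeans(zeta)
    }
    planted <- vapply(seq_len(L), function(j) {
      effect$centers[[j]] +
        (fas - fas_bar + eta[, j] + zeta[, j]) / (L * effect$slopes[j])
    }, numeric(n_subjects))
    planted <- matrix(planted, n_subjects, L,
                      dimnames = list(NULL, effect$target_features))
    jitter <- replicate(n_subjects, matrix(exp(rnorm(40, 0, 0.15)), 5, 8),
                        simplify = FALSE)
    extras <- tibble(
      p300_latency_ms = pmin(pmax(rnorm(n_subjects, 310, 25), 220), 480),
      p300_amplitude_uv = pmax(rnorm(n_subjects, 6, 1), 0.5),
      hrv_lf_amp = exp(rnorm(n_subjects, 0, 0.2)),
      hrv_hf_amp = exp(rnorm(n_subjects, 0, 0.2)),
      hr_bpm = pmax(rnorm(n_subjects, 70, 6), 45),
      eda_level = exp(rnorm(n_subjects, log(2), 0.3)),
      st_level = rnorm(n_subjects, 33, 0.5)
    )
    list(fas = fas, planted = planted, jitter = jitter, extras = extras)
  })

  ## validate planted values are realizable
  for (j in seq_len(L)) {
    f <- draws$planted[, j]
    if (effect$parsed[[j]]$type == "ratio" && any(f <= 0)) {
      abort(sprintf("planted values for '%s' are not all positive; adjust slope or center.",
                    effect$target_features[j]))
    }
    if (effect$parsed[[j]]$type == "np" && any(f <= -1)) {
      abort(sprintf("planted values for '%s' fall below -1; adjust slope or center.",
                    effect$target_features[j]))
    }
  }

  ids <- sprintf("S%02d", seq_len(n_subjects))
  profiles <- vector("list", n_subjects)
  bundles <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    base_amp <- default_band_amplitude() * draws$jitter[[i]]
    args <- c(
      list(subject_id = ids[i], fas_total = draws$fas[i],
           band_amplitude = base_amp),
      as.list(draws$extras[i, ])
    )
    args <- modifyList(args, profile_defaults)
    prof <- do.call(subject_profile, args)
    prof <- plant_effect(prof, effect, draws$planted[i, ])
    schedule <- generate_stimulus_schedule(seed = derive_seed(seed, 1000L + i))
    profiles[[i]] <- prof
    bundles[[i]] <- synthesize_recording(prof, schedule,
                                         seed = derive_seed(seed, 2000L + i))
  }
  names(bundles) <- names(profiles) <- ids

  truth <- tibble(
    subject_id = ids,
    fas_total = draws$fas,
    fatigue_class = fas_class(draws$fas)
  )
  truth <- dplyr::bind_cols(truth, as_tibble(draws$planted))

  structure(list(bundles = bundles, profiles = profiles, effect = effect,
                 seed = seed, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, seed %d\n",
              length(x$bundles), x$seed))
  cat(sprintf("  planted: %s (noise_sd = %s)\n",
              paste(x$effect$target_features, collapse = ", "),
              x$effect$noise_sd))
  invisible(x)
}

## largest-remainder allocation of n subjects to the class mix
allocate_classes <- function(n, class_mix) {
  p <- class_mix / sum(class_mix)
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * p - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  rep(names(class_mix), times = base)
}

## class-conditional FAS totals around the study's class means
draw_fas_total <- function(class) {
  spec <- switch(class,
    no_fatigue  = c(mean = 19, sd = 2, lo = 10, hi = 21),
    substantial = c(mean = 27, sd = 3, lo = 22, hi = 35),
    extreme     = c(mean = 37, sd = 3, lo = 36, hi = 50)
  )
  as.integer(min(max(round(rnorm(1, spec["mean"], spec["sd"])), spec["lo"]), spec["hi"]))
}

plant_effect <- function(profile, effect, planted) {
  ao <- profile$ao_band_amplitude
  ## normalized-power targets first (they fix a band's AO amplitude from
  ## baseline), then ratio targets (which reference the current AO amplitudes)
  ord <- order(vapply(effect$parsed, function(p) p$type != "np", logical(1)))
  for (j in ord) {
    p <- effect$parsed[[j]]
    f <- planted[[effect$target_features[j]]]
    if (p$type == "np") {
      ao[p$band, p$channel] <- profile$band_amplitude[p$band, p$channel] * sqrt(1 + f)
    } else {
      ao[p$b1, p$channel] <- sqrt(f) * ao[p$b2, p$channel]
    }
  }
  profile$ao_band_amplitude <- ao
  profile
}
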