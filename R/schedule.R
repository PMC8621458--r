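#' Generate an auditory-oddball stimulus schedule
#'
#' The oddball task presents `n_total` tones of two classes — frequent and
#' non-frequent — in randomized order at a fixed cadence: each stimulus lasts
#' `stim_dur_s` seconds and is followed by an inter-stimulus interval of
#' `isi_s` seconds, so onsets are `stim_dur_s + isi_s` apart starting at the
#' AO segment start. The default parameters give the standard 120-stimulus,
#' 80:20 task spanning the full 4-minute AO segment.
#'
#' @param n_total Total stimulus count (default 120).
#' @param frac_nonfrequent Proportion of non-frequent stimuli (default 0.2).
#'   `n_total * frac_nonfrequent` must be an integer.
#' @param stim_dur_s,isi_s Stimulus duration and inter-stimulus interval, s.
#' @param seed Integer seed; the label order is a seeded random permutation
#'   (counts are fixed, only the order is random).
#' @param ao_start_s Start of the AO segment within the session, seconds.
#'
#' @return A tibble (`marker_table`) with columns `onset_s`, `onset_sample`
#'   (0-based at 250 Hz, absolute within the session) and `label`.
#' @export
#' @examples
#' sched <- generate_stimulus_schedule(seed = 1)
#' table(sched$label)
generate_stimulus_schedule <- function(n_total = 120, frac_nonfrequent = 0.2,
                                       stim_dur_s = 1, isi_s = 1, seed = 1,
                                       ao_start_s = 60) {
  stopifnot_scalar_number(n_total, "n_total", min = 1)
  stopifnot_scalar_number(frac_nonfrequent, "frac_nonfrequent")
  if (frac_nonfrequent <= 0 || frac_nonfrequent >= 1) {
    abort("`frac_nonfrequent` must be strictly between 0 and 1.")
  }
  n_nf_real <- n_total * frac_nonfrequent
  n_nf <- round(n_nf_real)
  if (abs(n_nf_real - n_nf) > 1e-9) {
    abort(sprintf(
      "n_total * frac_nonfrequent = %s is not an integer; choose counts that divide exactly.",
      n_nf_real))
  }
  fs <- nf_eeg_fs()
  labels <- c(rep("nonfrequent", n_nf), rep("frequent", n_total - n_nf))
  labels <- withr::with_seed(seed, sample(labels))
  onset_s <- ao_start_s + (seq_len(n_total) - 1) * (stim_dur_s + isi_s)
  tibble(
    onset_s = onset_s,
    onset_sample = as.integer(round(onset_s * fs)),
    label = labels
  )
}
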