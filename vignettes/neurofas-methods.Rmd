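---
title: "Methods: fatigue estimation from five-minute wearable recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatigue estimation from five-minute wearable recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(neurofas)
```

## The estimation problem

Self-reported mental fatigue is measured by the Fatigue Assessment Scale
(FAS): ten items scored 1–5, a total of 10–50, and three conventional
classes — no fatigue (total ≤ 21), substantial (22–35), extreme (≥ 36). The
package estimates that total from one five-minute session recorded with a
consumer EEG headset and a wrist wearable: 30 s eyes closed (EC), 30 s eyes
open (EO), then a four-minute auditory oddball (AO) task of 120 tones (96
frequent, 24 non-frequent, 80:20, one second of tone plus one second of
silence). The EO segment serves as each subject's own spectral baseline; the
rare tones elicit the P300 event-related potential, whose amplitude tends to
fall and latency to rise with fatigue.

The estimator is deliberately simple: mass-univariate Pearson screening of
226 features against the FAS totals, a p-value ranking, and multiple linear
regression fit by the normal equation on the first *k* features, evaluated
with subject-level cross-validation. With cohorts of ~14 subjects, anything
richer would be unfalsifiable; the interest is in which features survive and
how little data (down to 15 s of the AO task) still predicts.

## Signal processing

**Filter chain.** A 60 Hz notch (RBJ biquad, Q = 30) followed by a
0.1–100 Hz Butterworth bandpass of design order 4, both applied
forward–backward (`filtfilt`), so the chain has zero phase lag and an
effective order of 8. The bandpass is realized as an order-4 high-pass at
0.1 Hz cascaded with an order-4 low-pass at 100 Hz: a direct 8-pole bandpass
with a normalized low edge of 8×10⁻⁴ is numerically fragile in double
precision, while the cascade is exactly equivalent in magnitude response and
stable. "Order 4" is read as the designed order before the
forward–backward pass, the common convention.

**Artifact subspace reconstruction (ASR).** The cleaning threshold is the
single printed parameter κ = 15. The implementation is the simplified
Euclidean variant: the calibration covariance *C* is estimated from a clean
baseline segment (EC by default; configurable, since the protocol does not
say which portion calibrated the cleaner). The signal is processed in 0.5-s
Hann-tapered windows with 50% overlap; in each window the principal
components *u* of the window itself are compared against the calibration:
a component with variance λ > κ² · uᵀCu is projected out, and the window is
rebuilt from the retained subspace and overlap-added. Thresholding
window-adapted components (rather than fixed calibration eigenvectors)
matters: a transient common to all channels concentrates in one window
component and is removed wholesale, whereas against the near-degenerate
eigenbasis of a clean-EEG covariance its energy would dilute below any
per-direction threshold. Two properties are contractual and tested: clean
windows pass through bit-exactly (no component over threshold means the
window is copied, not reconstructed), and a second pass changes nothing
beyond round-off. No Riemannian averaging and no automatic clean-window
search are attempted — with an explicitly provided calibration segment the
κ-semantics above are the whole algorithm.

**ERP stage.** Epochs span −200…+800 ms around each non-frequent onset on
the 4 ms grid (250 samples, onset at sample 50). The 0.1–10 Hz zero-phase
epoch filter is applied to the continuous recording before epoching, so
short epochs carry no filter edge transients. The average is
baseline-corrected by subtracting the channel's mean filtered EO amplitude —
the literal reading of "baseline (EO) corrected"; the conventional
pre-stimulus-mean baseline is available via `baseline = "prestim"`. The P300
amplitude is the maximum of the averaged waveform in the 200–500 ms window
and the latency its time, ties to the earliest sample; the maximum is
returned (with a warning) even when non-positive, since the definition is
silent about averages without a positive peak.

**Spectral stage.** Powers come from plain FFT periodograms of
non-overlapping 1-s windows aligned to segment starts (rectangular window;
Hann would trade leakage for bandwidth but the printed procedure says only
"FFT on 1-s windows"). Band power is the *sum* of periodogram ordinates over
the band's bins — the integral convention, under which white noise yields
power proportional to the band's bin count. At 250 Hz and 1-s windows the
resolution is 1 Hz and the printed band edges fall on bins; edges are
inclusive on both sides exactly as printed, so the 4 Hz bin counts in both δ
and θ (a `half_open` convention is available). Normalization is strictly
per subject: NP(t) = (AO(t) − ĒO)/ĒO per channel and band, where ĒO is the
mean over the 30 EO windows. The 20 ratios use powers prior to
normalization and are averaged across windows — the mean of per-window
ratios, the direct reading of "average power ratios"; a ratio of averaged
powers is a different estimator (Jensen's inequality) and is not what the
procedure describes.

**Wristband stage.** The PPG/BVP signal is analyzed directly — not via an
inter-beat tachogram — in 30-s windows advanced by 1 s, mean-removed, DC
dropped. Band membership at the 1/30 Hz resolution: the printed VLF upper
edge (0.03 Hz) lies below the first bin, so VLF collects all non-DC bins
below the LF lower edge (0.04 Hz), i.e. exactly the 0.0333 Hz bin. LF/HF
and LFNU = LF/(TP − VLF) are computed per window prior to normalization;
VLF/LF/HF/TP are EO-normalized like the EEG powers. IBI, HR, EDA and ST
enter as plain means over the (truncated) AO task — the normalization is
described only for the spectral quantities, so the slow streams are left
raw. For AO truncations shorter than 30 s the window shrinks to the
truncation length for both AO and EO, keeping the normalization
like-for-like; bands left without bins at the coarser resolution produce
`NA` features, and those columns are dropped from that duration's model
matrix.

## Modeling and evaluation

Selection computes, per feature, Pearson r against the FAS totals and the
two-tailed p-value from t = r√((m−2)/(1−r²)) on m−2 degrees of freedom;
features with p < α (default 0.05) are kept and sorted ascending by p, ties
broken by |r| descending then name — a fully deterministic ranking, which
k-prefix models require. Zero-variance columns get p = 1. No
multiple-testing correction is applied, on purpose: the screen is part of
the modeled procedure, and its type-I calibration (5% of pure-noise features
selected at α = 0.05, m = 14) is itself an acceptance test.

The NR-EEG variant prunes reciprocal ratio pairs on the same channel (α/θ
vs θ/α), dropping the larger-p member. The E4 variant ranks the six
wristband features (st, lf, tp, hf, lfnu, lf_hf) by p without the α gate.

Fitting uses the normal equations with the Moore–Penrose pseudo-inverse of
the Gram matrix, so rank-deficient designs (leave-one-out with large k, or
exactly collinear planted features) yield the minimum-norm solution with a
logged note instead of failing; an independent QR least-squares fit is the
test oracle.

Cross-validation is subject-level: 70:30 draws round(0.7 m) training
subjects (10 of 14), 80:20 draws 11, and LOO holds out one subject drawn
without replacement across the 10 repeats until all have served. "Ten-fold"
is read as ten random repeats of the split, matching the printed "randomly
selecting data from 10 subjects", not a partitioned 10-fold. Partitions are
drawn once per split scheme and reused across variants, durations and k, so
grid cells are comparable. Real-valued predictions are classified by the
midpoint extension of the integer class bins — cut points 21.5 and 35.5 —
because the integer bins say nothing about non-integer predictions.

Selection runs inside each training fold by default. The original
single-cohort protocol ranks features once on all subjects before
splitting — an optimistic leak at m = 14; it is kept available as
`selection_mode = "paper_faithful"` for comparison runs, but the
leakage-free mode is the default and the one the acceptance checks use.

## The synthetic cohort generator

The generator emulates the study conditions: 5-min sessions at the stated
rates, the 120-stimulus 80:20 schedule, a cohort class mix proportional to
3/8/6 (no/substantial/extreme) with class-conditional FAS totals around
19 ± 2, 27 ± 3 and 37 ± 3, P300 deflections as Gaussian bumps (σ = 40 ms,
per-subject latency ~310 ± 25 ms, amplitude ~6 ± 1 µV) time-locked to the
rare tones, PPG as two sinusoids at the planted LF/HF frequencies plus
noise, and tonic EDA/ST/HR/IBI levels with small drift. Baseline band
amplitudes default to δ/θ/α/β/γ = 10/6/8/4/2 µV RMS with 15% log-normal
inter-subject jitter; these are free parameters of the generator, not
study-matched values — the study does not report inter-subject spectral
variability.

EEG band noise is synthesized per 1-s block as random-phase harmonics on
the 1 Hz analysis grid, with each block's band power scaled exactly to the
profile amplitude. This is still band-limited noise, but it makes the
1-s-window FFT stage recover planted powers to machine precision — the
property that turns pipeline-level tests into exact parameter-recovery
tests rather than statistical ones. Two grid details follow from the
analysis conventions: δ is generated on bins 1–3 and θ on 5–7, leaving the
shared 4 Hz edge bin empty so both bands' inclusive-edge estimates stay
exact; and blocks are aligned to the segment starts, as the analysis windows
are.

Effects are planted by inverting feature definitions, never by relabeling:
a ratio target sets the numerator band's AO amplitude to √f times the
denominator's; a normalized-power target scales a band's AO amplitude by
√(1+f) against its own baseline. Feature values follow
f_ij = μ_j + (FAS_i − mean(FAS) + η_ij + ζ_ij) / (L·s_j), where s_j are the
planted slopes, η is scaled so the FAS residual SD equals `noise_sd`, and ζ
("style", default SD 1.5 FAS units) is drawn in the null space of the slope
vector: it decorrelates the target features — making the individual slopes
identifiable by regression — while leaving the planted linear relation
exact. With `style_sd = 0` the targets sit exactly on the plane (sample
correlation ±1), which is the configuration the perfect-recovery
acceptance test uses, because only a correlation of exactly ±1 guarantees
the planted trio outranks its own reciprocal ratios in every training fold.

What the generator does **not** emulate — and hence what passing tests do
not show about recorded data: volume conduction and channel correlation,
1/f spectral slopes, non-stationarity beyond block boundaries, eye-blink
and EMG artifacts (only idealized large transients used to exercise ASR),
pulse-wave morphology in the PPG, and any nonlinear feature–fatigue
relation. Recovery results on synthetic cohorts bound what the pipeline
can do when its assumptions hold; they say nothing about whether real EEG
carries the planted structure.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle: closed-form
formulas recoded directly, `cor.test` and QR least squares for the
statistics, brute-force argmax for peak detection, direct bivariate
simulation for planted correlations, and a permutation null for the
evaluation grid. Pipeline-level checks run on 14-subject cohorts (the
study's effective sample size) across all five AO durations; the P300
recovery check uses 20 seeded subjects with band-noise RMS at one fifth of
the deflection height and pools the eight channels per subject — the
deflection is common to all channels, and the ±10% amplitude budget already
absorbs the ~5% attenuation the 0.1–10 Hz epoch filter imposes on a
σ = 40 ms Gaussian. Selection calibration uses 1000 simulated 14-subject
cohorts of 226 pure-noise features. The perfect-recovery cohorts disable
the P300 bumps (`profile_defaults = list(p300_amplitude_uv = 0)`) and skip
the filter chain: stimulus-locked transients and passband ripple perturb AO
band powers at the 10⁻³ level, which is irrelevant for inference but above
the 10⁻⁶ exactness bar that test enforces; preprocessing belongs to runs on
recorded, artifact-laden data.

The permutation-null check deserves one honest caveat: with labels
permuted, a k-feature model fit on spurious correlations predicts around
the training mean with a spread of several FAS units, so held-out accuracy
sits slightly *below* the majority-class rate (≈ 38–43% against 50% at the
3/8/6-style mix) rather than at it. The acceptance band (majority ± 10
percentage points) accommodates this, but the offset is systematic, not
noise.

## Limitations

- The ASR variant is the simplified Euclidean form; results on heavily
  artifacted real recordings will differ from the full algorithm with
  automatic calibration selection.
- FAS reverse scoring defaults to none (the source protocol does not state
  it); the standard instrument reverses items 4 and 10 — set
  `reverse_items = c(4, 10)` in `score_fas()` if your administration does.
- With m ≈ 14 subjects, the p < 0.05 screen admits ~11 chance features out
  of 216; k-prefix models beyond the first few features fit noise. The grid
  reports standard errors across repeats for exactly this reason.
- LOO with k approaching m−1 is rank-deficient by construction; cells are
  fit by minimum-norm pseudo-inverse and flagged, not dropped.
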