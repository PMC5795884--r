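---
title: "Behind-the-ear EEG seizure detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behind-the-ear EEG seizure detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(earseiz)
```

## The problem

Long-term seizure monitoring needs EEG hardware that patients will actually
wear. A four-electrode montage glued behind the ears — two cross-head
derivations linking the left and right mastoid region (LC-RC, LT-RT) and two
unilateral derivations within one side (LT-LC, RT-RC) — is unobtrusive enough
for daily life, but it must be shown to carry the ictal signal and to support
automatic detection at a quality comparable to the full clinical 10-20 scalp
montage. `earseiz` implements that comparison as a reusable pipeline:

1. bipolar montage derivation and EDF/annotation I/O;
2. preprocessing: canonical-correlation blind source separation (BSSCCA) for
   muscle artifacts and a 0.5–35 Hz zero-phase band-pass;
3. blink-EOG quantification via ICA;
4. magnitude-squared coherence between each ear channel and every scalp
   channel during seizures ("best matchup");
5. band-power feature extraction on 2 s windows;
6. patient-specific RBF-SVM detection with leave-one-seizure-out evaluation,
   scored by sensitivity and false-detection rate (FDR).

Hospital EEG of the reference cohort is not distributable, so the package
ships a seeded synthetic generator with the statistical structure the
analysis assumes; every stage is tested against that generator's ground
truth. The reference cohort's metadata (12 patients, 47 seizures, 431 h) and
its published per-patient best-matchup coherence table ship as plain-CSV
fixtures (`load_patient_metadata()`, `load_matchup_reference()`).

## The synthetic generator

`sim_config()` fixes the study conditions; `simulate_recording()` composes
additive, independently seeded injectors on a 26-electrode referential
recording (10-20 set + sphenoidals + LT/LC/RT/RC, referenced to Fpz, 250 Hz):

* **Background** — a few shared `1/f^β` sources (β = 1) with smooth Gaussian
  gain maps over a flattened head layout (spatial correlation as a
  volume-conduction surrogate), an 8–12 Hz alpha source weighted toward
  O1/O2, and independent per-electrode `1/f` noise; ~15 µV RMS per electrode.
* **Blinks** — a 300 ms raised-cosine bump from a single midline anterior
  source with Gaussian falloff (λ = 0.6 head units), gains normalized to 1 at
  Fp1/Fp2. At `asymmetry = 0` homologous left/right gains are *exactly*
  equal, so cross-head derivations cancel the blink identically — the
  geometric mechanism behind the clinical observation that blink EOG is
  absent behind the ear. Default 15/min, peak 50–70 µV.
* **Seizures** — amplitude-modulated 3–5 Hz rhythm (default 4 Hz) plus a weak
  second harmonic, 60 s, 150 µV at the focus electrode (a clearly
  supra-background, high-SNR discharge), gains decaying with layout distance
  from the focus; ipsilateral gains strictly exceed their mirror images.
* **EMG** — Hann-windowed 20–35 Hz noise bursts on temporal/auricular
  electrodes; **electrode faults** — a high-amplitude rhythmic or step
  artifact on one referential electrode, which phase-reverses across bipolar
  channels sharing it.

What the generator does **not** emulate: biophysical head conduction
(BEM/FEM), sleep architecture, cardiac artifacts, non-stationary background
drift, inter-seizure morphology variability, or the artifact burden of
ambulatory recordings. Green tests therefore demonstrate that the pipeline's
machinery is correct and self-consistent under the stated assumptions — not
that clinical performance figures transfer to real patients.

### Desk scale

The clinical protocol extracts 1 h epochs around each seizure and five 1 h
seizure-free epochs per 24 h. The packaged cohort runs at desk scale:
**10-minute epochs**, 2 seizure-free epochs per patient, 600 s guard, with
seizure counts, focus sides and lobes mirroring the metadata fixture (47
seizures over 12 pseudo-patients). `cohort_configs(epoch_len_s = 3600,
n_nonseizure = 5, guard_s = 1800)` restores the clinical scale.

## Preprocessing choices

* **Band-pass** — cascaded 4th-order Butterworth high-pass (0.5 Hz) and
  low-pass (35 Hz), zero phase. The squared-magnitude response is applied in
  the frequency domain, which is the forward–backward (filtfilt) steady state
  and O(n log n) on multi-hour recordings; a single 8-pole band-pass with a
  70× corner ratio is numerically fragile. DC is rejected exactly; 10 Hz
  passes within 0.5%; 50 Hz is attenuated below 0.06.
* **BSSCCA** — per 10 s window, CCA between the multichannel signal and its
  1-sample-delayed copy ranks sources by lag autocorrelation; sources below
  0.30 are zeroed and the window is rebuilt from the rest. The algebra runs
  on the signal's principal subspace, so rank-deficient mixtures (fewer
  sources than channels) are handled rather than rejected; threshold 0 is an
  exact identity and reconstruction never increases centred power. Scalp and
  ear channels are denoised jointly (they share one amplifier and reference);
  a config flag is unnecessary because the function takes whatever channels
  it is given.
* **Epoching** — half-open `[t0, t1)` windows, `floor(t · fs)` sample
  mapping, onset anchored at 50% of the epoch, clipped (not padded) at
  recording edges. Seizure-free epochs are drawn uniformly over admissible
  start times at least `guard_s` from any annotation, non-overlapping,
  deterministic under the seed.

## Blink-EOG quantification

ICA (symmetric FastICA, logcosh contrast, PCA whitening, seeded) decomposes
the 22-channel scalp montage; the component most correlated with Fp2-F8 is
selected automatically (|r| < 0.2 flags low confidence; a manual override
exists because the clinical procedure is visual inspection). The component is
rescaled to microvolts through its mixing weight onto Fp2-F8, peaks within
30–80 µV are detected with a 0.25 s refractory interval, ±0.2 s epochs are
averaged per channel, and the EOG amplitude is the ±0.1 s mean of the
average. Edge-truncated epochs are dropped.

Two deliberate choices:

* FastICA stops at `max_iter` with a warning rather than an error when the
  trailing, near-Gaussian components fail to settle — they have no fixed
  point to settle into, while the strongly non-Gaussian blink component
  stabilizes early. Requesting more components than the signal rank, or a
  divergent iteration, still errors.
* Blink morphology is quantified on the **unfiltered** derivations. The
  0.5 Hz zero-phase high-pass of the detection path undershoots around a
  300 ms transient and biases the ±0.1 s mean roughly 20% low (38.1 → 29.4 µV
  on a noiseless injected blink); nothing in the EOG procedure requires the
  detection band-pass, and the averaging over many epochs already suppresses
  background drift.

## Spectral comparison

Welch estimates use 2 s Hann segments at 50% overlap (0.5 Hz resolution —
the 2–20 Hz comparison band then spans 37 bins). Coherence
`Cxy = |Gxy|² / (Gxx·Gyy)` is formed from the averaged cross- and
auto-spectra; at least 8 averaging segments are required because
single-segment coherence is identically 1. Per seizure, the band mean over
2–20 Hz (closed) is computed on the annotated ictal interval and averaged
across seizures; the scalp channel with the highest average is the best
matchup, ties resolved by montage order. Report tables round half away from
zero to 2 decimals and use the sample SD (n − 1) — with the packaged
reference table this reproduces column summaries of 0.83/0.83/0.82/0.80 and
an RT-RC SD of 0.07, which population SD would not.

## Features

Per channel and 2 s window: fifteen mean powers over 1–2, 1.5–2.5, …, 7–8,
8–14 and 14–20 Hz, plus the peak frequency in 1–20 Hz; 16 features per
channel concatenated channel-major (22 × 16 = 352 scalp, 4 × 16 = 64 ear).
The per-window spectrum is a single Hann periodogram (500 samples → 0.5 Hz
bins): Welch sub-averaging inside 2 s would leave fewer than 3 bins per 1 Hz
band. Band membership is by bin-centre inclusion on closed intervals, so
every band holds ≥ 3 bins; "mean power" is the mean of PSD bins (flagged
interpretive — band-integrated power differs only by a constant 0.5 Hz
factor per bin and would rescale, not reorder, features). Windows are
non-overlapping by default and labelled seizure when their midpoint falls in
an annotation. An all-zero window reports zero powers and peak frequency 0
with a degenerate flag.

## Detection

The detector is the standard soft-margin SVM with Gaussian kernel
`K(x, y) = exp(−‖x−y‖² / 2σ²)`, fit by libsvm (e1071) on z-scored features
(training statistics; constant features get unit scale — RBF kernels need
comparable scales). Class weights are inversely proportional to class
frequency: ~21 positive windows against hundreds of negatives would
otherwise collapse the fit to all-negative.

* **Grid** — c and σ on decade steps over [10⁻³, 10³] (7 × 7).
* **Inner CV** — stratified 3-fold at the window level, scored by *balanced*
  error (mean of per-class error rates). Three folds rather than five keep at
  least 7 positives in every validation fold at desk scale and cut the grid
  cost 40%; plain error would be minimized by the all-negative rule at this
  imbalance, which cannot be what "lowest probability of error" is meant to
  select. Ties prefer smaller c, then smaller σ.
* **Selection subsample** — the inner CV runs on a seeded stratified
  subsample of at most `max_inner_negatives = 100` negative windows (decade
  grids need only a coarse error landscape); the winning pair is refit on the
  full training set. Purely a runtime measure, exposed in `svm_config()`.
* **Degeneracy guards** — inverse-frequency weighting balances the aggregate
  class weights exactly, so at vanishing c the weighted SVM is a knife-edge
  constant classifier whose side can differ between the selection subsample
  and the full refit. Two guards fix this: a constant prediction on an inner
  validation fold scores chance (0.5), and if the winning pair's refit is
  constant on its own training data, the remaining candidates with inner
  error below chance are tried in rank order (if none qualifies the
  top-ranked model is kept — the honest outcome on channels that carry no
  ictal signal).
* **Events** — runs of ≥ 2 consecutive positive windows (4 s) become
  declared events; events closer than 30 s merge. The clinical report never
  defines the window→event rule, so both knobs are config.
* **Scoring** — a seizure is detected when any event overlaps its
  annotation; every non-overlapping event is one false detection; the FDR
  denominator is the hours of *tested seizure epochs*, per the clinical
  definition. Patients with a single seizure are evaluated with their only
  seizure's onset windows in training (flagged via the report attribute) —
  the only protocol consistent with evaluating such patients at all.

```{r detection-example}
cfgs <- cohort_configs(seed = 1)
sim <- simulate_recording(cfgs[[3]])
prep <- preprocess_patient(sim, seed = 7)
pf <- prepare_patient_features(prep$ear$seizure_epochs,
                               prep$ear$nonseizure_epochs)
loo_evaluate(pf, svm_config(), label = "ear")
```

## Numerical and degenerate-input conventions

* Half-open time intervals everywhere; `floor(t · fs)` sample mapping.
* EDF export calibrates each electrode to a symmetric 2-decimal physical
  range covering its extremes; round-trip error is bounded by the 16-bit
  quantization step.
* Coherence with fewer than 8 Welch segments errors (degenerate estimate);
  zero-power bins yield coherence 0, not NaN.
* A single-patient matchup column reports SD 0 with `sd_defined = FALSE`.
* Zero paired differences are dropped before signed ranking; the exact null
  distribution is built by generating-function convolution over doubled
  midranks, so it stays exact under ties (n ≤ 25; beyond that a
  tie-corrected normal approximation with continuity correction is used).
* Rank-deficient BSSCCA windows are retained unchanged with a warning.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on synthetic data:
12 pseudo-patients × 10-minute epochs (47 seizures) for the full detection
comparison, 6 pseudo-patients for the acceptance script's detection section,
3 × 10-minute subjects for the blink-symmetry analysis, 30 s 8-channel
mixtures for the BSSCCA checks, and 30 s two-channel segments for the
direct-DFT coherence oracle. These sizes are the package's desk-scale
defaults; all of them scale up through the same configs.

## Known limitations

* Synthetic seizures are stationary narrowband rhythms; real ictal patterns
  evolve in frequency and morphology, so absolute sensitivity/FDR on the
  synthetic cohort is not a clinical estimate.
* The ictal amplitude is a free parameter (no quantitative distribution is
  published for the reference cohort); only relative and recovery properties
  are asserted.
* The EOG component is selected by frontal correlation, which can latch onto
  frontal slow artifacts other than blinks in pathological recordings — the
  manual override exists for that case.
* The blink spatial model is a single midline source; lateral eye movements
  (saccades) are out of scope.
* Coherence is the classical magnitude-squared form; volume-conduction
  inflation is not corrected (no imaginary coherency), matching the
  comparison the package reproduces.
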