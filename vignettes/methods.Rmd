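---
title: "Predicting voice pitch and intensity from facial and neck sEMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting voice pitch and intensity from facial and neck sEMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emg2prosody)
```

## The problem

Silent-speech interfaces reconstruct speech from non-acoustic signals such
as surface electromyography (sEMG) of the face and neck. Classic sEMG
interfaces recover *what* was said but not *how* — the prosody: pitch
(fundamental frequency, f0) and loudness (intensity, dB SPL). This package
implements a complete research pipeline for regressing continuous f0 and
intensity contours from 8-channel sEMG recorded synchronously with audio:

1. **Alignment** — each sEMG channel is time-aligned to the audio with
   exact dynamic time warping (DTW) at a 10-ms hop.
2. **Targets** — f0 is tracked with a normalized-autocorrelation candidate
   generator plus a dynamic-programming path finder (floor 65 Hz, ceiling
   475 Hz); intensity is the squared signal smoothed by a unit-area Kaiser
   window, calibrated to dB SPL from a sound-level-meter reading.
3. **Features** — per 40 ms/20 ms frame (f0 stream) or 150 ms/30 ms frame
   (intensity stream), twenty feature families per channel: six
   time-domain statistics, nine periodogram statistics, 24 MFCCs, twelve
   Daubechies-2 wavelet statistics, plus coherence, beta-band coherence
   and peak cross-correlation over unordered channel pairs (516 features
   for 8 channels after removing symmetric duplicates).
4. **Preparation** — task-stratified 80-20 test holdout, 5-fold CV of the
   rest (a 60-20-20 split per fold), Gaussian-noise augmentation of the
   training rows, PCA retaining 90% of the variance.
5. **Regression** — feed-forward networks with GeLU hidden layers, a
   single linear output unit, MSE loss and Adam; four schemes
   (single/multi speaker x f0/intensity) differing in target transform,
   optimizer defaults, and a batch-norm flag.
6. **Evaluation** — MAPE, Pearson r, Lin's concordance correlation (CCC),
   RMSE and mean bias error (MBE = mean(predicted - observed)); the fold
   with the highest validation CCC supplies the final model.

Because the human recordings this kind of study uses are not public, the
package ships a synthetic-session generator with known ground truth, and
all quantitative claims are property-based: tracker accuracy on known
pitches, metric identities, DTW oracle equivalence, and end-to-end
recovery of the generator's prosody from its sEMG.

## The synthetic world

`generate_session()` produces one recording: voiced audio plus 8 sEMG
channels at 2222 Hz band-limited to 20–450 Hz (the acquisition band of
wireless differential sensors), with truth contours on a 5-ms grid.

**Audio.** An impulse train at the instantaneous period (phase obtained by
integrating f0) excites a two-pole resonator near 500 Hz — one formant's
worth of shaping, enough for an autocorrelation tracker, deliberately far
from a full speech synthesizer. The waveform's short-time RMS is then
forced to the intensity trajectory (reference: full-scale sine = 91 dB)
and noise is added at 30 dB SNR. Unvoiced spans are silent; their truth
intensity is pinned 30 dB below the habitual level, since silence does not
sit at the speaking level.

**sEMG.** Each channel is band-passed Gaussian noise amplitude-modulated by
an activation envelope — the standard interference-pattern model — plus a
noise floor at 0.05 of the peak envelope. The envelope is
`softplus(a + g_f * f0_dev_ST + g_i * intensity_dev_dB + g_v * voicing)`,
with per-channel gains drawn once from the seed. Pitch deviation is
referenced to the speaker's habitual f0 (120 Hz default) so constant-pitch
tasks still carry pitch information.

**Gain calibration (a priori).** The generator's stated purpose is to make
downstream recovery testable, so the f0 gains are sized from an explicit
noise calculation rather than tuned on outcomes: a 40-ms frame of
band-limited noise at 2222 Hz has about `2 * B * T ~ 34` degrees of
freedom, giving a log-RMS estimation noise of ~17% per channel per frame.
For the f0-induced envelope modulation to clear that floor across 8
channels at sub-semitone resolution, `d log(env) / dST ~ g_f * 0.5` must
exceed ~0.12, i.e. `|g_f| >~ 0.24`; gains are drawn from ±U(0.22, 0.40).
Intensity gains U(0.08, 0.18) and voicing gains U(0.8, 1.6) make the
envelope dominated by loudness and voicing, with pitch as a secondary
modulation — the intended difficulty ordering. These values are reported
with every recovery result and were fixed before the acceptance runs.

**What the generator does not emulate.** Articulatory cross-talk, electrode
lift and motion artifacts, firing-rate spectral changes, inter-speaker
anatomy, and any phonetic content. A green end-to-end test therefore
establishes that the pipeline recovers prosody *when the coupling is of
the stated form and strength* — not that real sEMG supports the same
accuracy.

## Numerical choices

* **Pitch tracker.** Frames of `3 / f_min` with a Gaussian taper; the
  normalized autocorrelation is divided by the window's autocorrelation;
  candidate peaks are refined by parabolic interpolation; path costs use
  the published defaults (silence 0.03, voicing 0.45, octave 0.01,
  octave-jump 0.35, voiced/unvoiced 0.14). Strengths above 1 are folded
  back (`1/r`) to tame numerically spurious maxima.
* **Intensity.** DC is removed before squaring. The Kaiser shape parameter
  is `20 * pi / sqrt(2)` (sidelobes far below -190 dB); since the window
  is normalized to unit area, the contour is insensitive to the exact
  value. All-silent input clamps at a documented -200 dB floor rather
  than -Inf. The dB reference makes a full-scale sine read ~91 dB; the
  reference cancels after SPL calibration.
* **Frame grids.** Feature frames and target frames both start at exact
  multiples of the step; start indices are rounded per frame so the grid
  never drifts from the contour grid over long recordings. A target frame
  is undefined when less than half its span (configurable) carries defined
  contour values; undefined f0 frames are dropped before modelling.
* **DTW features.** The representation the alignment consumes is not fixed
  by the method's definition, and our choice matters: per-10-ms log-energy
  plus four band energies, z-scored per track, smoothed over 5 hops, plus
  a constant-offset dummy dimension (2 z-units). The smoothing controls
  the variance of short-window EMG energy estimates; the dummy dimension
  adds a near-constant cost per path cell, so the optimal path does not
  trade length for chance cross-modal level matches. Without it, aligning
  an *already aligned* pair wanders several hops off the diagonal (~50%
  within ±1 hop); with it the path is diagonal (100% within ±1 hop) while
  a constructed 100-ms delay is still recovered exactly. Both DTW solvers
  themselves remain pure Euclidean-cost dynamic programming; the
  low-memory variant is the divide-and-conquer midpoint method and is
  tested cell-for-cell against the quadratic oracle.
* **Wavelets.** The db2 transform is periodized on frames zero-padded to a
  multiple of 16, keeping the transform exactly orthogonal (detail +
  approximation energy equals frame energy to 1e-8); four levels because
  each wavelet statistic has dimension 4.
* **Beta coherence.** With Welch segments of 32 samples at 2222 Hz the bin
  spacing is 69 Hz, so the 15–30 Hz beta band contains no full bin; the
  bins overlapping the band are used instead (documented, deterministic).
* **Spectral moments** are unnormalized `sum(P * f^k)`, k = 1..3;
  "power-density wavelength" is waveform length applied to the
  periodogram curve.
* **ZC/SSC dead-band**: 0.01 of the frame RMS.
* **Network training.** Inputs (PCA scores) and targets are standardized
  with training statistics inside `train_model()`; raw dB SPL targets sit
  near 70 and would otherwise need thousands of Adam steps just to move
  the output bias. Losses are reported in the caller's units. Early
  stopping restores the best-validation weights. Predictions are rounded
  to 0.01 ST / 0.01 dB SPL at the output only.
* **PCA.** Features are z-scored first (the families differ in scale by
  orders of magnitude); constant columns get zero loading. The retained
  count is the smallest reaching 90% cumulative variance and is logged —
  on the synthetic suite it lands near 150-250 of 516, the same order as
  the ~100 of 593 a comparable real-data pipeline reports.
* **MAPE for f0** is computed on the Hz scale (the ST scale crosses zero
  when referenced to the speaker mean, making MAPE ill-defined);
  intensity MAPE on dB SPL. Observations below 1e-6 in magnitude are
  excluded and counted.
* **Seeds.** One master seed fans out to every consumer through
  `derive_seed(seed, stream_name)` (a fixed integer recurrence), so any
  stage can be reproduced bit-identically from its manifest.

## Design decisions that were genuinely open

* **Feature dimension.** The printed battery (20 families over 8 channels,
  symmetric duplicates removed) does not arithmetically reach the
  published 593; this implementation documents its realized dimension
  (516 = 8 x 51 per-channel + 3 x 36 unordered pairs) in the feature
  matrix header instead of forcing a count.
* **Pairwise families** are computed once per unordered pair, self-pairs
  included (their constant entries are discarded by PCA).
* **PCA and augmentation are fit per fold on that fold's training portion
  only.** The alternative (fitting on all data) risks leakage; the
  no-leakage route is asserted by recomputing fold statistics from the
  training indices alone.
* **Augmentation scale** (no published value): one noisy copy per training
  row at 0.1 of each feature's SD, in the original feature space, before
  PCA.
* **Architectures** (no textual specification of hidden-layer sizes
  exists for this family of models): single-speaker default 512-256-128, multi-speaker 1024-512-256-128,
  GeLU throughout, no dropout or weight decay (augmentation and CV are the
  regularizers). The end-to-end acceptance runs a reduced 64-32 network
  with 60 epochs to fit a single-CPU budget; recovery, not capacity, is
  the property under test.
* **Recording-atomic splitting** is available through the `groups`
  argument of `stratified_split()` (whole recordings stay in one
  partition), but the default splits at frame level within task strata,
  matching the stated splitting unit.

## Known limitations

* The pitch tracker implements the autocorrelation method faithfully but
  is validated on synthetic sources only; no claim is made of
  bit-compatibility with any specific analysis program.
* Overlapping analysis frames mean adjacent frames share signal; a
  frame-level random split therefore has optimistic leakage relative to a
  recording-atomic split. This matches the pipeline being emulated and is
  flagged rather than silently changed.
* The multi-speaker schemes are implemented and unit-tested (transforms,
  batch norm) but the acceptance suite exercises the single-speaker
  schemes; a multi-speaker acceptance would need a population of synthetic
  speakers with calibrated anatomical variation, which the generator
  deliberately does not model.
* `dtw_lowmem` recomputes distances during divide-and-conquer, trading
  ~2x time for O(N+M) memory — the intended trade-off.
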