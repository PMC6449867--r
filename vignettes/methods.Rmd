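---
title: "Sleep staging from tracheal body sound and actigraphy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging from tracheal body sound and actigraphy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnostage)
```

## The measurement problem

Type-4 ambulatory sleep monitors record one or two channels and trade the
rich physiology of polysomnography (PSG) for comfort and simplicity. The
device modeled by this package records a single tracheal body-sound channel
(5 kHz) and a 6-axis IMU on the thoracic belt (250 Hz). Sleep stages are
not observable directly without EEG; the working hypothesis of
cardiorespiratory sleep staging is that autonomic state leaves a footprint
in breathing regularity, heart-rate variability (HRV) and gross body
movement that differs between wake, REM and the non-REM depths. The
package turns the two raw channels into a 30-dimensional feature vector
per 30-second epoch and classifies each epoch with a linear discriminant
into one of three stage systems:

* **s2** — wake (W) vs. sleep (S, all of REM and N1–N3);
* **s3** — W / REM / NREM (N1–N3);
* **s4** — W / REM / light sleep (N1+N2) / deep sleep (N3).

Every design choice below is a package decision unless it is forced by the
physics of the signals; tunables live in `somnostage_config()` with the
defaults given here.

## Respiratory chain

The breathing-band path is: FIR band-pass 200–2000 Hz → spectral
subtraction of a noise template → short-term envelope → threshold
detection of breath runs.

* **Band-pass.** Linear-phase Hamming-window FIR with compensated group
  delay, so breath onsets keep their timing. Order scales with the sample
  rate (~312 taps at 5 kHz), giving a transition band of ~50 Hz and more
  than 50 dB of stopband attenuation — heart sounds (below ~100 Hz) and
  mains hum are removed.
* **Noise template.** The mean Hann-windowed magnitude spectrum of the
  quietest 10% of 1024-sample frames (energy-ranked). Quiet-frame ranking
  keeps breath bursts and other transients out of the template.
* **Spectral subtraction.** Per frame (1024 samples, half-overlap,
  periodic Hann), the magnitude is reduced by `alpha` times the template
  and floored at 1% of itself; the phase is kept and frames are
  overlap-added, which reconstructs the input exactly when nothing is
  subtracted. The default `alpha = 2` over-subtracts deliberately: the
  magnitudes of stationary noise are Rayleigh-spread around their mean, so
  subtracting exactly the mean leaves ~20% residual energy, while a factor
  of 2 removes essentially all of it at a small cost in weak signal.
* **Envelope.** Short-term RMS, `E = sqrt(mean(x_i^2))` per 200-ms window
  hopped every 50 ms — long enough to smooth in-band noise to a stable
  floor, short enough to resolve 0.3-s breath sounds. A mean-absolute
  variant is available (`resp$envelope_kind = "mean_abs"`); the two track
  each other up to a scale on realistic signals.
* **Breath detection.** The "no breathing" line is adaptive:
  1.2 × median envelope. The median sits on the inter-breath floor as long
  as breathing occupies less than half the record, so the rule transfers
  across recordings and gains. Threshold runs lasting 0.3–10 s become
  breaths (onset = run start, amplitude = run maximum); breath-to-breath
  (BB) intervals outside 1–15 s (4–60 breaths/min) are discarded before
  any statistics.

Thirteen features per epoch: breathing rate, mean/SD/CV/RMSSD/range and
lag-1 autocorrelation of BB intervals, mean/SD/CV of breath amplitude,
envelope energy, fraction of the epoch above the breathing threshold, and
the envelope's spectral peak in 0.1–0.5 Hz. A 30-s epoch holds only ~5–8
breaths, far too few for variability statistics, so interval statistics
use the epoch ± 60 s; amplitude and energy features stay within the epoch.

## Cardiac chain

Heart sounds S1 and S2 survive band-limiting to 5–30 Hz while breathing
sound (200 Hz and above) does not. The path is: decimate to 250 Hz
(anti-aliased) → zero-phase band-pass 5–30 Hz → envelope peak detection →
S1/S2 pairing → gap interpolation → HRV features.

* **Peak detection.** Local maxima of a 40-ms moving-average magnitude
  envelope above `median + k·MAD`. The 5–30 Hz band is narrow, which makes
  the noise envelope broadly spread (relative MAD ≈ 0.5); with the
  textbook `k = 3` the threshold sits near the 99th percentile and pure
  background noise fires about once per second. The default is therefore
  `k = 5`, which we measured to admit ≲ 1 spurious peak per 20 s of noise
  while remaining an order of magnitude below genuine heart-sound peaks.
  A local-prominence gate (a peak must reach 25% of the strongest envelope
  value within ± 0.35 s) removes the sidelobe trains that sharp band
  edges ring around loud sounds; S2, at roughly half of S1, passes easily.
* **Pairing.** Among all peak pairs whose gap lies in the S1–S2
  plausibility window 0.15–0.45 s, repeatedly take the globally smallest
  gap with both peaks unused; each pair is one beat, timed at its first
  peak (the S1, analogous to the ECG R peak). Unpaired peaks are
  discarded. Beats closer than the minimum plausible NN interval (0.33 s,
  180 bpm) are deduplicated. An exhaustive restatement of the same
  minimal-distance rule guards the efficient implementation in the tests.
* **Interpolation.** Coupling loss and movement artefacts leave gaps.
  A gap exceeding 1.5 × the rolling median of the 10 preceding detected NN
  intervals is filled with evenly spaced beats at approximately that
  median spacing, and the inserted beats are flagged; the interpolated
  fraction is itself a feature, so the classifier can discount artefacted
  epochs. A gap at the start of a recording has no preceding context and
  stays unfilled.

Thirteen features per epoch: mean HR, mean NN, SDNN, RMSSD, pNN50, CV,
lag-1 autocorrelation, LF power (0.04–0.15 Hz), HF power (0.15–0.4 Hz),
LF/HF, normalized LF, interpolated fraction, NN range. Time-domain
statistics use the epoch ± 60 s; spectral HRV needs several minutes of
tachogram, so LF/HF uses the epoch ± 120 s with the NN series linearly
resampled at 4 Hz and a periodogram integrated over the bands. All
cardiac features depend only on event times, hence are exactly invariant
to audio gain.

## Movement chain

The IMU is fused into a quaternion orientation by the Madgwick
gradient-descent complementary filter (gyroscope integration corrected
toward the accelerometer's gravity direction, gain `beta = 0.1` rad/s —
the published stable range; a zero-norm accelerometer sample degrades to a
gyro-only step). Sleeping position is read off the gravity direction in
the sensor frame: the nearest of five mounting directions (supine, prone,
left, right, upright) under the declared mounting convention (sensor z
dorsal-ventral, y cranial-caudal, x to the subject's left — configurable,
since devices differ). Ties at sector boundaries resolve by that priority
order. The labeling uses only the gravity direction, so it is invariant
to yaw. A 5-sample hysteresis absorbs jitter at sector boundaries before
position changes are counted.

Four features per epoch: dominant position (per-sample mode), number of
position changes, mean `| ||accel|| − g |` (gravity-magnitude
subtraction, which does not depend on fusion accuracy during vigorous
movement), and mean gyroscope magnitude.

## Classifier

A Gaussian linear discriminant with pooled within-class covariance:

`delta_k(x) = x' S^{-1} mu_k − mu_k' S^{-1} mu_k / 2 + log pi_k`

* Features are normalized by training-set mean and SD — global, not
  per-subject; subject-specific normalization is deliberately out of
  scope (a home-screening classifier must work without calibration).
* With 30 features and rare classes (deep sleep can contribute few
  epochs), the plain pooled covariance estimate is fragile, so it is
  shrunk toward its diagonal: `S* = (1 − lambda) S + lambda diag(S)`,
  `lambda = 0.1` by default. `lambda = 0` reproduces a classical LDA fit,
  which an independent implementation cross-checks in the tests.
* Priors default to training class frequencies; uniform priors are a
  config switch.
* Posteriors are the softmax of the discriminants; exact ties break
  toward W, then class order — a conservative choice, since calling wake
  is the safer screening error.
* No temporal smoothing is applied to the predicted hypnogram by default.

## Validation layer

* **LOOCV.** Train on all subjects but one, predict the held-out subject,
  rotate until each has been tested once. Per-stage accuracy (recall of
  each reference stage) is reported both averaged over folds and from the
  pooled confusion matrix, because "averaging over all data sets" is
  ambiguous between the two; the same duality is provided for the
  unweighted Cohen kappa. A fold whose training set lacks a class is
  flagged, skipped and excluded from the averages.
* **Sleep summary.** TST/TWT/SE from the 2-stage hypnogram at 0.5 min per
  epoch; WASO counts wake after the first sleep epoch (an alternative
  "first of three consecutive sleep epochs" onset rule is available; the
  default is the simpler rule, and an all-wake night has WASO 0).
* **SE groups.** 0–39 / 40–59 / 60–79 / ≥ 80%, half-open with the
  boundary in the upper group (SE = 40 is "40–59").
* **Screening.** At each threshold, subjects are classified by estimated
  SE ≥ threshold and compared with the reference grouping: sensitivity,
  specificity, PPV, NPV, binary kappa, and a ROC obtained by sweeping the
  decision threshold over the continuous estimated SE. The trapezoidal
  AUC of that sweep equals the Mann–Whitney probability (ties counted
  half), which the tests assert exactly. Degenerate sides (no subject
  below a threshold) yield NA rather than a fabricated rate.

## Synthetic nights

No clinical recordings ship with the package; the generator produces
stage-annotated nights with the statistical structure the chain relies
on, so every claim above is testable end to end.

* **Hypnogram.** First-order Markov chain over 30-s epochs, starting in
  W. Two anchor matrices describe a consolidated and a severely
  fragmented sleeper; `wake_bias` in [0, 1] interpolates between them,
  and a cohort spreads its subjects across that range
  (`cohort_wake_bias()`), emulating a sleep-clinic referral population
  whose sleep efficiencies span from below 40% to above 90%.
* **Physiology.** Per-stage parameters (defaults in
  `default_stage_params()`) encode the literature-motivated directions:
  deep sleep is slow and regular (12 breaths/min at CV 0.05, 55 bpm at
  SDNN 20 ms), REM is fast and irregular (18 breaths/min at CV 0.30,
  SDNN 70 ms), wake is movement-rich (60 bursts/h vs. ≤ 6 in sleep). BB
  intervals are gamma-distributed so the realized mean and CV equal the
  configured ones exactly; NN intervals superpose LF (0.095 Hz) and HF
  (0.24 Hz) sinusoids, amplitude-split to the configured LF/HF ratio and
  SDNN, plus white jitter.
* **Audio.** Breaths are Hann-gated white noise bursts band-limited to
  200–2000 Hz; beats are pairs of 20 Hz Gabor pulses 0.3 s apart (S2 at
  60% of S1) superimposed on the breath sound so the two band-separated
  extractors face real crosstalk; white background noise is added at a
  configured SNR (breath-burst power over noise power; 10 dB default,
  `Inf` disables noise). The IMU stream is the gravity vector of the
  current position, 3-s great-circle rotations with matching gyroscope
  rates at position changes, Poisson movement bursts at the stage's rate
  and a small sensor noise floor.
* **Determinism.** One seed drives everything; cohort subjects derive
  per-subject seeds (`seed + 7919 i`, kept below 2^31), so any subject
  can be regenerated alone.

What the generator does **not** emulate: real tracheal acoustics (snoring,
wheezes, swallowing), apnea events, EEG-defined stage boundaries, drift in
microphone coupling, or between-subject differences in baseline physiology
(every synthetic subject shares the per-stage parameter table, differing
only in architecture and realization noise). Passing the end-to-end tests
therefore demonstrates that the chain is implemented correctly and
recovers the structure it assumes — not that it attains any particular
accuracy on clinical recordings, where subject variability is known to be
the limiting factor.

## Numerical choices and degenerate inputs

* Epoch grids are half-open `[30k, 30(k+1))`; trailing partial epochs are
  discarded; a 1e-9 relative epsilon guards duration computations against
  sample-rate round-off from file round trips.
* Epochs without events yield NA features flagged for imputation; the
  assembly step fills them with the recording median of the feature (0 if
  a feature is degenerate everywhere), so the classifier always sees a
  finite matrix and the flags remain available.
* Constant interval series report CV 0 and lag-1 autocorrelation 0 (the
  estimator is undefined there; 0 is the uninformative value).
* Spectral subtraction requires hop = frame/2, where the periodic-Hann
  analysis windows sum to exactly 1 and reconstruction is exact to
  rounding.
* Cohen's kappa returns 1 (perfect) or 0 (with a warning) when chance
  agreement is exactly 1, the only case where its denominator vanishes.

## Problem sizes used in the shipped validation

The test-suite and the acceptance script exercise: 5-minute single-stage
fixtures for breath (15/min, BB CV 0.15, SNR 10 dB) and beat (60 bpm,
SDNN 50 ms, SNR 10 dB) detection; a 10-subject cohort of 2-hour nights at
default physiology for staging, SE estimation and screening; and the
first 4 of those subjects for stage-conditional parameter recovery.
Recovery is measured on stage-run *interior* epochs (both ± 2 neighbors in
the same stage) because the ± 60 s feature context deliberately spans
neighboring epochs, which biases transition epochs toward their
neighbors' physiology; the interior restriction measures the
stage-conditional parameter the generator actually set.

## Known limitations

* The envelope threshold is global per recording; a night with dramatic
  gain drift would need block-wise thresholds.
* Pairing assumes two audible sounds per beat; pathologies with absent S2
  would halve the detected rate (the NN plausibility gate would flag
  this as heavy interpolation).
* The LD classifier is linear by design; no claim is made that the
  feature set is linearly separable on clinical data.
* Position classification presumes the declared mounting; a rotated
  sensor mislabels positions (but movement activity features are
  mounting-invariant).
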