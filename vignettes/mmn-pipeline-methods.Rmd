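---
title: "Methods: sensor-space MMN analysis with verifiable synthetic EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-space MMN analysis with verifiable synthetic EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnpipe)
```

## The scientific problem

The mismatch negativity (MMN) is a fronto-central negative deflection of the
event-related potential (ERP) elicited roughly 100-200 ms after a rare
"deviant" sound interrupts a stream of repeated "standards". Its amplitude is
modulated in opposite directions by whole-form lexical storage (stored forms
elicit a larger MMN) and combinatorial congruency (ungrammatical combinations
elicit a larger MMN), which makes it a usable probe of whether complex words
are stored or composed. The design analyzed here is a 2x2 within-subject
oddball experiment: two stem standards (ROOT factor) each combined with two
derivational suffixes (SUFFIX factor), giving four deviant conditions whose
crossed congruency predicts a cross-over ROOT x SUFFIX interaction in the MMN
window.

`mmnpipe` implements the full sensor-space chain for such experiments —
oddball sequence generation, ERP preprocessing, plus-minus signal-to-noise
quality control, region-of-interest (ROI) window ANOVA, and a cluster-mass
permutation test on electrode-plane x time volumes — together with a
synthetic-EEG generator that emulates the recordings with known ground-truth
effects, so that every stage can be verified without access to raw data.

## Oddball design

A block contains 630 standards (the first 15 a consecutive habituation run)
and two deviant types presented 105 times each at a fixed 2 s stimulus onset
asynchrony, with 3-5 standards between consecutive deviants. These published
counts are arithmetically incompatible with the gap bound: 209 inter-deviant
gaps of at least 3 require `15 + 209 x 3 = 642 > 630` standards. The counts
are the testable published quantities, so `generate_block()` treats them as
authoritative and relaxes the minimal number of gap lower bounds (never below
1, chosen at seeded random); with the defaults exactly 12 gaps shrink to 2,
and the count is reported in `relaxed_gap_count`. Habituation trials and
standards immediately following a deviant are flagged and excluded from
averages. Block order is counterbalanced over the participant index.

## The synthetic generator

`simulate_recording()` builds continuous multichannel data as
`1/f^alpha`-shaped Gaussian background noise (per-channel SD 4 uV, alpha = 1,
30% of variance shared across EEG channels so scalp noise is spatially
correlated) plus per-trial evoked components:

* an obligatory auditory onset response (Hann kernel, peak -3.5 uV, latency
  100 ms, half-width 50 ms) for every stimulus, evoked again at the acoustic
  divergence point of deviants (the suffix is a second acoustic onset);
* the MMN kernel for deviants: a Hann window of half-width 20 ms centered
  155 ms after the divergence point (so the default kernel spans exactly the
  135-175 ms analysis window), scaled by a condition amplitude map and
  per-trial jitter (SD 0.5 uV), with a Gaussian spatial profile (SD 1.0
  plane-radians) centered on the FCz site of the azimuthal-equidistant
  projection.

All evoked activity lags the event marker by 25 ms, emulating the stimulus
delivery delay that the preprocessing trigger shift compensates; this makes
the +25 ms shift a consequential, testable step rather than a no-op.

The default amplitude map (`sicherheit` -5.5, `sicherkeit` -3.0,
`sauberheit` -2.0, `sauberkeit` -4.5 uV) encodes the congruency cross-over
plus a root-frequency offset, giving an interaction contrast of -5.0 uV at
the kernel peak. The study reports effect sizes only as F statistics, so
these amplitudes are explicitly synthetic choices. They were fixed once, at
design time, from the closed-form ground truth (`ground_truth()`): a nominal
subject's pooled-deviant ROI signal RMS in the 100-200 ms QC window is about
1.5-1.8 uV, comfortably above the 1 uV exclusion floor — i.e. the generator
emulates a *retained* participant, as the cohort-construction targets
require. Between-subject variability enters as a per-condition amplitude
perturbation (SD 0.7 uV).

Artifacts are injected with an exact log: blinks (Hann deflections, opposite
polarity above/below the eye, steep periocular falloff so they barely reach
central sites), square-pulse jumps placed inside the analysis epoch of
logged trials (150 uV, large enough to survive the band-pass and trip the
default rejection), and bad channels replaced by 50 uV `1/f` noise (colored,
not white, so the fault remains detectable after band-limiting).

What the generator does *not* emulate: realistic cortical source geometry
and volume conduction (the spatial profile is a single Gaussian), later ERP
components beyond the configured kernels, non-stationary noise, muscle or
line artifacts, and drifting electrode impedance. Passing tests therefore
demonstrate the correctness and calibration of the *analysis machinery*
under a plausible signal model, not robustness to every failure mode of real
recordings.

## Preprocessing

The chain mirrors the study's order: EOG derivation (`vEOG = upper - lower`,
`hEOG = vEOG - lateral`), zero-phase band-pass, decimation to 200 Hz,
bad-channel handling, linear decomposition with EOG-correlation screening,
spherical-spline interpolation, divergence-locked epoching (-50...800 ms,
half-open grid, 170 samples at 200 Hz), 50 ms baseline correction, and
rejection at strictly >120 uV range or >25 uV sample-to-sample jumps (EEG
channels only — ocular channels carry blinks by design and are handled by
component screening, not trial rejection).

Numerical choices worth recording:

* **Filter.** A linear-phase FIR built as the difference of two unit-gain
  Hamming-windowed-sinc low-passes: the DC gain is exactly zero by
  construction, and symmetric application with reflection padding gives
  exactly zero group delay, preserving the component latencies the analysis
  windows depend on. The default length `3.3 * rate / lo` (~11000 taps at
  1000 Hz) sets the transition band near the 0.3 Hz corner; reduced-scale
  runs use 4001 taps.
* **Decimation.** Integer-factor decimation (1000 to 200 Hz is the study's
  case) with event indices rescaled and rounded; the band-pass already
  bounds the spectrum far below the target Nyquist frequency.
* **Decomposer.** The unmixing algorithm is pluggable; the tested logic is
  the screening rule (flag iff |Pearson r| with vEOG or hEOG strictly
  exceeds 0.3, mirroring the quoted open inequalities) and the
  reconstruction with flagged components zeroed. The default decomposer is
  varimax-rotated PCA: the rotation localizes spatial loadings, so the
  spatially compact ocular pattern separates from broad evoked topographies
  instead of mixing with them along variance-ordered axes (raw PCA
  occasionally let the evoked component absorb enough blink content to
  cross the screening threshold and be removed). Screening runs on the
  continuous, pre-epoch signal, matching the stated order of steps.
* **Bad channels.** By-eye inspection is irreproducible; a variance
  threshold (SD beyond 5x or below 1/5 of the median EEG channel SD) stands
  in, and interpolation is the Perrin-style spherical spline (stiffness
  m = 4, 50 Legendre terms, ridge 1e-5) — exact for constant fields, <2%
  error for first-order harmonics on a 128-channel cap.
* **Epoch grid.** Half-open `[tmin, tmax)` with the `t = 0` sample included
  gives unambiguous sample counts (`round((tmax - tmin) * rate)`), and a
  sub-nanosecond tolerance guards window selection against floating-point
  drift of the time axis. The trigger shift is applied in seconds after
  decimation, which is invariant to the rate.

## Quality control

The plus-minus (polarity-flip) estimate averages all kept deviant epochs
with every second one (even chronological indices — a deterministic,
seed-free choice) sign-flipped: a trial-invariant signal cancels exactly and
the residual estimates the ERP noise floor. An odd epoch is dropped from the
end. The SNR statistic averages over the ROI first, then takes the RMS over
the 100-200 ms window, for signal and noise ("average RMS" is ambiguous in
prose; the per-channel-RMS-then-average ordering is available behind a
flag, and RMS is also used for the 1 uV signal floor, for consistency with
the SNR definition). A participant is excluded iff SNR < 1 (strict), signal
RMS < 1 uV (strict), or an externally supplied flag (e.g. muscle artifacts,
mirroring the study's manual judgment) is set.

## Sensor statistics

Window means are taken over the fronto-central ROI (for synthetic montages:
the 46 EEG channels nearest the FCz site on the projected plane; the
published ROI is shown only graphically, so the ROI is always configurable
and never hard-coded) and the four analysis windows 40-80, 135-175, 230-270
and 340-500 ms. The 2x2 repeated-measures ANOVA is computed from
per-subject contrast scores; for two-level within-subject factors the
contrast F with df (1, n-1) is exactly the classical decomposition F and
the squared paired t, which the tests verify against an independent
sums-of-squares oracle and `aov()`'s error strata. Planned comparisons are
paired F tests, uncorrected, as in the source analysis; no correction is
applied across the four windows (mirrored deliberately — a known
limitation).

For the cluster test, ERPs are scattered onto a 32x32 (default)
azimuthal-equidistant grid — electrode-bearing cells take the channel value
exactly, remaining in-hull cells a thin-plate-spline value at the cell
center (node-exact, reproduces affine fields; chosen over piecewise-linear
triangulation as the standard smooth scatter interpolant) — and stacked
with time as the third axis. Voxel-wise interaction F maps are thresholded
at `f_critical(alpha, 1, n - 1)` (4.24 at n = 26), suprathreshold voxels
are labelled under face (6-neighbour) connectivity, and each cluster is
weighed by its summed F. The null distribution of the maximum cluster mass
comes from sign-flipping every subject's contrast volume independently with
probability one half — exact under within-subject exchangeability of the
factor labelling — over 1000 seeded iterations by default. The p-value
convention is `#(null >= mass) / n_perm`, matching the printed arithmetic
"heavier than 965 of 1000 maxima gives p = 0.035"; ties count toward the
null, and the `(k + 1)/(n + 1)` convention is available behind a flag. The
labelling and permutation loop are implemented in C++ for throughput; an
independent R flood-fill oracle checks the labelling in the tests.

## Calibration and problem sizes

The test suite verifies, at reduced problem sizes chosen to keep the full
run in minutes on a single core:

* **Type-I error** — 200 null cohorts (all condition amplitudes equal,
  n = 12 subjects, 16x16 grid x 40 frames, 500 permutations), generated at
  the ERP level by `simulate_erp_cohort()` (the statistics consume
  subject-level ERPs, so simulating continuous recordings for calibration
  cohorts would add runtime without adding evidence): the fraction of
  cohorts with any cluster p < 0.05 must lie within the exact binomial 95%
  interval around 0.05.
* **Parameter recovery** — 20 cohorts of n = 26 with the default effects:
  the ROI ANOVA interaction must reject at alpha = 0.05 in at least 18, and
  in every rejecting cohort the heaviest significant cluster's time extent
  must overlap 135-175 ms.
* **Cohort retention** — a 33-subject cohort with 5 subjects constructed to
  fail the SNR/signal rules (no evoked activity at all) and 2 externally
  flagged, run through the full continuous-recording pipeline at reduced
  scale (32 EEG + 3 EOG channels, one block of 60 standards + 2 x 10
  deviants, 4001-tap FIR), must retain 26. `scripts/acceptance.R` recomputes
  this quantity from scratch at any seed.

## Known limitations

Vendor EEG formats (BrainVision, EDF) are not read; the pipeline is
exercised on the synthetic container, and recordings live in memory with
plain-text serialization (event and QC tables as CSV, results as JSON,
montages as `.sfp`). Rational (non-integer) resampling factors are not
supported. The decomposer is not an ICA; for real data with rich artifact
structure, an ICA decomposition can be plugged in through the same
`mmn_decomposition` interface. Source-space analysis (forward modelling,
inversion, source statistics) is out of scope.
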