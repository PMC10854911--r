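---
title: "Methods: spectral detection of unconsciousness and brain death in gas-stunned poultry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral detection of unconsciousness and brain death in gas-stunned poultry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(stunEEG)
```

## Scientific setting

During controlled-atmosphere stunning, broiler chickens are lowered into a
pit filled with a CO~2~/N~2~ mixture. Two transitions matter for welfare
assessment:

* **loss of consciousness (LOC)** — after which the bird cannot perceive the
  aversive gas; behaviourally proxied by **loss of posture (LOP)**;
* **brain death** — after which recovery is impossible; proxied by a
  collapse of EEG power and, behaviourally, by the bird becoming motionless.

Both are inferred from a single-channel EEG through its short-time power
spectrum. This vignette documents the models, parameters and numerical
choices the package uses. Every problem size shown here (cohort sizes,
durations) is the package's own choice for illustration; none is a claim
about any particular animal experiment.

## Spectral processing chain

1. **Band-pass filter, 1–30 Hz, zero phase.** Detection thresholds concern
   the Delta (1–4 Hz) to Beta (13–32 Hz) range; the filter removes movement
   and mains contamination. `bandpass()` realises the filter in the frequency
   domain: the FFT of the whole trace is multiplied by the squared magnitude
   response of an order-4 Butterworth design, `1/(1+(f/f_hi)^8) ·
   1/(1+(f_lo/f)^8)`, and inverse-transformed. This is the frequency-domain
   equivalent of forward–backward (`filtfilt`) filtering: exactly zero phase
   shift, so detected onset times are not biased by filter delay. It is also
   numerically robust for a 1 Hz corner at a 1 kHz sampling rate, where a
   time-domain IIR realisation has poles very close to the unit circle.
2. **Epoching.** `epoch_split()` cuts each recording phase (baseline,
   exposure) into non-overlapping 1 s epochs; partial trailing epochs are
   discarded. Onset times are reported as the start of the first epoch of a
   qualifying run, in seconds from gas-exposure start.
3. **Welch spectrum per epoch.** `power_spectrum()` averages Hamming-windowed
   1024-point FFT segments with 50% overlap (a 1 s epoch at 1 kHz is a single
   zero-padded segment). The window is power-normalised so the summed
   spectrum approximates the epoch's mean square; the zero-frequency bin is
   removed.
4. **Features.** `spectral_features()` derives total power Ptot (µV²), the
   median frequency F50 and spectral edge F95 (smallest grid frequencies at
   which cumulative power reaches 50% and 95% of Ptot), and fractional band
   contributions over Delta 1–4, Theta 4–8, Alpha 8–13, Beta 13–32 and Gamma
   32–200 Hz (each band takes `lower < f ≤ upper`; the Gamma cap shrinks to
   the Nyquist frequency when needed). Band fractions are normalised by total
   in-band power so they sum to one.

## Detection rules

All thresholds live in `detection_config()`; defaults in parentheses.

* **Baseline.** Per-bird medians of F50, Delta fraction and Ptot over the
  pre-exposure epochs, after excluding epochs with F50 below the artifact
  floor (4 Hz) — low-frequency transients caused by bird movement would
  otherwise bias the Delta reference.
* **LOC.** An exposure epoch qualifies when F50 falls below 50% of the
  baseline median (criterion A) and/or the Delta fraction exceeds the
  baseline median by 65% (criterion B). The combiner is configurable
  (`either`, the default, or `both`); Delta can also be compared against an
  absolute fraction. LOC is the start of the first run of ≥ 4 consecutive
  qualifying epochs.
* **Spectral death.** Same persistence rule on `Ptot < 10%` of the baseline
  median.
* **Isoelectric trace.** An absolute rule, independent of baseline:
  `Ptot < 2.5 µV²` for ≥ 4 consecutive epochs. Epochs with zero power count
  as isoelectric (a flat-zero trace is the extreme of the pattern) but break
  the baseline-relative runs, whose ratios they leave undefined.
* **Quality.** After 1–30 Hz filtering the Gamma band lies outside the
  passband, so its residual share of total power measures broadband noise;
  `gamma_quality()` flags a recording when any epoch reaches 2%.

```{r}
sim <- simulate_eeg_trace(eeg_sim_spec(t_loc_true = 25, t_death_true = 65,
                                       seed = 2))
analyze_bird(sim$trace)
```

## The synthetic EEG generator

`simulate_eeg_trace()` synthesises a trace as a sum of amplitude-modulated
narrowband oscillators — one to three fixed-frequency components per band
(2.5; 5.1, 6.9; 9.0, 11.2; 14.6, 19.5, 24.4 Hz), each with a random phase, a
small per-bird frequency jitter (±0.15 Hz) and a slow sinusoidal amplitude
modulation — plus a band-limited (1–30 Hz) Gaussian background of 5 µV².
Band powers cross-fade linearly from the conscious profile (Delta 55, Theta
45, Alpha 80, Beta 45 µV²) to the unconscious one (110, 40, 20, 10 µV²) over
`transition_width` (2 s) starting at the programmed LOC time; after the
programmed death time the signal decays exponentially (τ = 1 s) to a
broadband floor of 1 µV RMS, below the isoelectric threshold. Sparse 1.5 Hz
raised-cosine bursts model movement artifacts on the conscious baseline.

The choice of oscillators rather than pure filtered noise per band is
deliberate: real EEG is rhythmic, and a single 1 s epoch of band-limited
Gaussian noise has so much variance in its band-power estimates (relative
standard deviation near 60% for a 3-bin band) that epoch-wise threshold
rules would fire essentially at random. Narrowband oscillators give stable
per-epoch features while the Gaussian background keeps spectra realistic.
The generator does **not** attempt to emulate burst suppression,
electrode-contact changes, or inter-individual differences in absolute
amplitude — it is a test harness with controllable, auditable spectral
statistics, not a biophysical model.

Cohorts (`simulate_cohort()`, `default_eeg_cohort()`) draw per-bird LOC and
death times from truncated normal distributions in the mean ± sd form in
which such onsets are reported, and derive an independent RNG substream per
bird from the master seed, so single birds are reproducible in isolation.

## Behaviour module

`default_ethogram()` fixes the catalogue: two anchors occurring exactly once
(loss of posture, motionless), six state behaviours carrying durations and
five point behaviours carrying counts, each restricted to before/after LOP
or both. `partition_by_lop()` splits each bird's timeline at its LOP anchor
— state events spanning the anchor are split so that durations are conserved
exactly — and `cohort_tables()` aggregates per-treatment proportions, event
counts and durations. Group comparisons use a hand-written Pearson
chi-squared on proportions and a pooled/Welch two-sample t
(`chi_square_proportions()`, `two_sample_t()`), both cross-checked in the
test suite against `stats::chisq.test()` and `stats::t.test()`.

## Gas profiles and compliance

`simulate_gas_profile()` produces per-cycle CO~2~/O~2~ series: piecewise
constant phase targets, an initial linear ramp from ambient air over the
lift-descent time (23 s), and clamped Gaussian measurement noise.
`check_gas_compliance()` compares per-phase means against the treatment
definition (e.g. two-phase CO~2~: below 40% CO~2~ in the first half, above
90% CO~2~ with O~2~ below 2% in the second), optionally excluding the
descent window.

## Reproducibility

`run_pipeline()` derives every stage's RNG stream from one master seed and
writes CSV outputs plus a JSON manifest of MD5 checksums with no timestamps;
re-running a configuration reproduces the output files byte for byte. All
random draws are wrapped so the caller's global RNG state is left untouched.

```{r}
out <- run_pipeline(run_config(seed = 11, out_dir = tempfile(),
                               eeg_treatments = "40C60N", n_eeg = 1,
                               behaviour_treatments = "40C60N",
                               n_behaviour = 3))
out$detection
```

## Limitations

* Onset ground truth in simulations is an instant; real transitions are
  gradual, and the 4-epoch persistence rule systematically reports onsets a
  few seconds after the programmed time. The acceptance tests therefore
  check one-sided recovery windows rather than unbiased estimates.
* The EDF support is a deliberately minimal single-channel subset (1 s
  records, 16-bit samples) sufficient for this pipeline, not a general EDF
  implementation.
* Statistical summaries use classical tests on per-bird values; no
  hierarchical (cycle-level random effect) model is fitted.
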