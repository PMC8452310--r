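---
title: "Slow and fast switchers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow and fast switchers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchwave)
```

## The model

Sleep slow waves are high-amplitude delta-band (< 4 Hz) NREM oscillations:
a hyperpolarized negative phase (down-state) followed by a depolarized
positive phase (up-state). The speed of the down-to-up transition is a
marker of how efficiently cortical networks switch from silence to massive
firing, but the classical measure of transition speed — the slope — scales
with wave amplitude, which confounds comparisons across ages and subjects.

This package is built around a per-wave statistic that does not: the
**transition frequency**. If `tau` is the delay from the wave's maximum
negative point to its maximum positive point, the transition frequency is

$$f_\tau = \frac{1}{2\tau},$$

the frequency of the half-wave spanned by the depolarization transition.
A transition of 200 ms corresponds to 2.5 Hz. Across a night of sleep the
distribution of `f_tau` is bimodal: a low-frequency population of **slow
switchers** and a high-frequency population of **fast switchers**. The
distribution is modelled as a two-component Gaussian mixture

$$p(f_\tau) = p_{slow}\,g(f_\tau;\mu_1,\sigma_1)
            + p_{fast}\,g(f_\tau;\mu_2,\sigma_2),
  \qquad p_{slow} + p_{fast} = 1,$$

fitted per subject by EM. The crossing frequency `f*` where the two
weighted component densities intersect is the classification boundary: a
wave is a slow switcher iff `f_tau < f*` (ties go to fast; the boundary
has measure zero for the model but the rule must be total). Three further
analyses hang off this classification:

* **Event-locked connectivity.** At six phases of each wave — five evenly
  spaced from the hyperpolarization trough (phase −π) to the
  depolarization peak (phase 0), plus one after the peak (+π/4) — the
  phase lag index between the detection channel n\* and every other
  channel m is the mean over waves of `sign(sin(phi_n* - phi_m))`. It is
  blind to zero-lag (volume-conducted) synchrony and saturates at ±1 for
  a constant non-vanishing propagation delay. The two detection
  directions of a pair are averaged (keeping the argument order of the
  phase difference fixed, so true propagation reinforces rather than
  cancels), significance is assessed with a max-statistics resampling
  null at p = 0.01, and the **global connectivity index** sums |PLI| over
  the significant pairs.
* **Cycle dynamics.** The percentage of each switcher class per sleep
  cycle (relative to the class total across the night) declines across
  the first three cycles; the decline is fitted as an exponential decay
  `a e^{-rt}` or an exponential reduction `a - b e^{rt}` over the 1-based
  cycle index.
* **Spindle co-occurrence.** A wave co-occurs with a spindle when a
  same-channel spindle onset falls at wave phase in `[-π, π/2]`; the
  mixture and connectivity analyses can be stratified by this flag.

## Detection parameters

Values are fixed at the analysis constants and exposed as arguments:

| parameter | default | unit | role |
|---|---|---|---|
| detection band | 0.3–4.0 | Hz | zero-phase band-pass before wave detection (−3 dB at the edges, > 23 dB down at 0.1/4.2 Hz) |
| negative peak | < −40 | µV | wave criterion |
| peak-to-peak | > 75 | µV | wave criterion |
| negative deflection | 0.125–1.5 | s | wave criterion (inclusive bounds) |
| positive deflection | ≤ 1.0 | s | wave criterion |
| phase band | 0.16–4.0 | Hz | Hilbert phase of each wave; wider at the low end so the slowest waves keep a full cycle |
| sigma band | 10–16 | Hz | linear-phase FIR for spindle detection |
| envelope threshold | 75th percentile | — | per channel, over artifact-free N2/N3 samples |
| spindle duration | 0.5–3 | s | inclusive |
| connectivity p | 0.01 | — | family-wise, max-statistics |
| minimum events | 20 | waves | per detection channel |

Waves are segmented between successive negative-going zero crossings of
the delta-filtered trace, with the negative deflection ending at the first
positive-going crossing; the criteria bounds are applied inclusively (the
printed criteria do not state the crossing convention or boundary
behavior; these are the simplest total rules). Both band-pass filters are
symmetric FIR designs applied with exact group-delay compensation, which
is mathematically zero-phase; the design cutoffs are calibrated by
bisection so the *realized* −3 dB points land on the stated edges (a
windowed design otherwise puts the cutoff near −6 dB). Peak times are
refined by three-point parabolic interpolation to reduce the 1/sr
quantization of `f_tau`. The Hilbert envelope of the sigma band is
smoothed with a 200 ms moving average and supra-threshold runs closer
than 100 ms are merged before the duration filter (smoothing width and
merge gap are not fixed by the criteria; these are conventional values).

## The synthetic generator

Real polysomnography with consented sharing is not available to this
package, so `generateRecording()` produces the statistical structure the
analysis assumes, with ground truth:

* 1/f^a background noise per channel (default a = 1, broadband SD 15 µV);
* biphasic slow waves — half-cosine negative then positive lobe with
  independently settable durations, trough-to-peak delay equal to the
  drawn `tau` — whose `tau` comes from a two-mode Gaussian (slow mode
  0.55 ± 0.10 s, fast mode 0.28 ± 0.04 s, i.e. transition frequencies
  ≈ 0.91 and 1.79 Hz, straddling the 1.2 Hz boundary);
* per-class event rates 2.5/min of NREM in cycle 1, decaying as
  `exp(-r (cycle - 1))` with r = 1.3 (slow) and 1.6 (fast) by default;
* every event appears on every channel shifted by a cumulative 10 ms
  per channel index, giving each channel pair a constant non-vanishing
  delay — the structure the PLI is designed to detect;
* optionally a Hann-windowed 13 Hz spindle (0.5–1.5 s, onset at wave
  phase −π/4) coupled to a configurable fraction of waves;
* a deterministic block hypnogram (25% N2, 55% N3, 20% REM per cycle,
  default three cycles of 20 minutes).

All randomness derives from one master seed through a fixed splitting
scheme (`substream k = (seed * 1009 + k) mod (2^31 - 1)`), so identical
configurations are bit-identical. Twenty-minute cycles keep a full
three-cycle night computable in seconds while preserving the event-count
statistics; event rates, amplitudes and the tau modes are realistic for
frontal derivations in young adults. What the generator does **not**
emulate: realistic sleep microstructure (K-complexes, arousals, stage
transitions), amplitude/tau correlations within waves (assumed
independent; not asserted as physiology), scalp topography, or
non-stationary noise. Passing tests on this generator therefore
demonstrate the correctness of the computations, not the clinical
performance of the detectors.

## Numerical choices

* **tau on the filtered trace.** Peaks are located on the delta-filtered
  signal, consistent with detection. Band-limiting rounds the extrema of
  narrow waves, which biases the fast mode's recovered transition
  frequency upward by roughly 5–10%; recovery checks on synthetic data
  use a 0.25 Hz tolerance on the fast mode for this reason.
* **Phase maps.** The analytic signal is taken over a window extending
  one wave length beyond the wave on each side, then cropped; waves whose
  unwrapped phase is non-monotone or escapes `[-3π/2, π/2]` beyond
  tolerance are flagged and excluded from connectivity (counted, not
  dropped from the event table).
* **EM.** k-means++-style initialization, 10 restarts, variance floor
  1e-4 Hz², convergence when the log-likelihood gain falls below 1e-6
  relative to the log-likelihood scale, at most 3000 iterations; the `k = 1`
  fit is the closed-form MLE. `f*` is the root of the quadratic obtained
  by equating the weighted component log-densities, keeping the root
  between the means.
* **Model order.** AIC = 2·(3k−1) − 2·logLik is computed for k = 1…kMax
  and the smallest k within 2 AIC units of the minimum is selected — the
  conventional equivalence band, preferring the sparse decomposition.
  Plain argmin is available (`sparsityDelta = 0`) but overselects:
  AIC is not a consistent order selector for mixtures, and its
  probability of preferring k = 3 on genuinely two-component data does
  not vanish with sample size (we verified the likelihood gaps against
  an independent mixture implementation). Even with the sparsity band,
  expect the true order on roughly three quarters of seeded replicates
  of the standard bimodal fixture, not near-certainty; the test suite
  records this honestly.
* **Connectivity null.** The null resamples the non-detection channels'
  phases as independent uniform draws per event (per channel, per
  resample), 1000 resamples by default, threshold at the empirical
  (1−p) quantile of the per-resample maximum |PLI| over all pairs.
  Permuting event indices instead would *not* be a valid null here: a
  constant inter-channel lag — the effect under test — survives any
  permutation of events, so a permutation null reproduces the signal
  and has no power. Thresholding and the GCI use |PLI|, making the
  statistic direction-agnostic.
* **Decay fits.** Nonlinear least squares with the amplitude parameters
  profiled out (linear in `a`, or `(a, b)`, for fixed r) and a 1-D
  search over r on [0, 20]; exact on noise-free model-generated
  percentages to 1e-6. With the form unspecified both are fitted and
  the higher R² wins, ties to the two-parameter decay. Only cycles 1–3
  enter by default. Constant percentages are a perfect r = 0 decay
  (R² defined as 1 when both SSE and SST vanish). The reduction form is
  parameterized as `a - b e^{rt}` with the offset free, since the bare
  exponential has no scale for percentages.
* **EDF.** 16-bit EDF export/import is implemented directly (ASCII
  header, little-endian integer records, per-channel symmetric physical
  range), giving a quantization step of `2 max|x| / 65535` µV.

## Problem sizes

The test suite exercises the full pipeline on compressed nights (4–6
channels, 6–8 minute cycles) and the statistical properties on their
natural sizes: mixture recovery and model order on 20 replicates of
n = 2000, the family-wise error of the max-statistics null on 500 seeded
null datasets (4 channels, 30 events, 500 resamples), and connectivity
power on 200-event planted-lag fixtures. `scripts/acceptance.R` runs the
generator at its full default conditions (19 channels, three 20-minute
cycles, ~2000 planted wave instances) with 1000 resamples per phase
point. These sizes were chosen so each property is measured at meaningful
precision while a complete run stays in the minutes range on one core.

## Known limitations

* The detectors implement the stated criteria literally; on data whose
  sigma envelope is not spindle-dominated, a pure percentile threshold
  flags ~25% of samples by construction and yields liberal detections.
  Real NREM sigma activity (and the burst-rich test fixtures) place the
  75th percentile above the noise floor.
* Transition delays measured on the band-limited trace are slightly
  compressed for the narrowest waves (see above).
* Connectivity assumes enough waves per detection channel (default 20);
  channels below the minimum contribute phases but no directed rows.
* The generator's propagation model (one cumulative constant lag per
  channel index) makes essentially all channel pairs connected; it is a
  power fixture, not a topography model.
* Group-level statistics on real cohorts (ANOVA and follow-ups) are out
  of scope; the pipeline exports the tidy per-subject tables such tests
  consume.
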