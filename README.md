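# switchwave

Sleep slow waves — the high-amplitude delta (< 4 Hz) oscillations of NREM
sleep — are not one population. Classified by how fast each wave swings
from its hyperpolarized trough to its depolarized peak, they split into
**slow switchers** and **fast switchers**, two families with different
EEG connectivity signatures and different rates of homeostatic decline
across the night. `switchwave` implements that analysis end to end for
multichannel scalp EEG, for sleep researchers who have a referenced
recording, a 30-s-epoch hypnogram with cycle labels, and an artifact
mask.

The statistic at the core is the per-wave **transition frequency**

> f<sub>τ</sub> = 1 / (2τ),

where τ is the delay from the wave's maximum negative point to its
maximum positive point (a 200 ms transition ↔ 2.5 Hz). Per subject, the
f<sub>τ</sub> distribution is fitted with a two-component Gaussian
mixture p(f<sub>τ</sub>) = p<sub>slow</sub>·g(f<sub>τ</sub>; μ₁, σ₁) +
p<sub>fast</sub>·g(f<sub>τ</sub>; μ₂, σ₂) by EM, the number of
components is checked with AIC, and the crossing frequency f\* of the two
weighted densities (≈ 1.2 Hz) labels every wave: slow switcher iff
f<sub>τ</sub> < f\*. Around the classification the package provides:

* slow-wave detection on the 0.3–4 Hz zero-phase filtered signal
  (negative peak < −40 µV, peak-to-peak > 75 µV, negative deflection
  125–1500 ms, positive deflection ≤ 1000 ms, artifact-free N2/N3 only);
* spindle detection (10–16 Hz linear-phase FIR, smoothed Hilbert
  envelope over the 75th percentile, 0.5–3 s) and wave–spindle
  co-occurrence via the wave-phase window [−π, π/2];
* per-wave Hilbert phase maps in the 0.16–4 Hz band, anchored at 0 on
  the depolarization maximum and spanning [−3π/2, π/2];
* event-locked **phase lag index** connectivity,
  pli(n\*, m) = ⟨sign sin(φ<sub>n\*</sub> − φ<sub>m</sub>)⟩, at six wave
  phases, symmetrized over detection directions, thresholded by a
  max-statistics resampling null (p = 0.01), and summarized by the
  **global connectivity index** (sum of |PLI| over significant pairs);
* per-cycle switcher percentages and exponential decline fits
  (decay a·e<sup>−rt</sup> or reduction a − b·e<sup>rt</sup>);
* a seeded synthetic polysomnography generator (1/f background, planted
  biphasic waves with a two-mode τ distribution, coupled spindles,
  constant inter-channel propagation lags, cycle-structured event rates)
  with full ground truth, plus EDF/hypnogram/CSV/JSON interchange.

## Worked example

A full synthetic night at the default study conditions (19 channels at
256 Hz, three 20-minute cycles), analysed end to end:

```r
library(switchwave)
cfg <- runConfig(synthetic = syntheticConfig(seed = 42),
                 outDir = "switcher-run", seed = 42)
res <- runPipeline(cfg)
#> recording: 19 channels, 60.0 min
#> slow waves detected: 1871
#> spindles detected: 4252
#> waves with co-occurring spindle: 952
#> AIC-selected components: 5; f* = 1.212 Hz; p(slow) = 0.468

res$mixture
#> SwitcherMixture: 2 Gaussian component(s), n = 1871, logLik = -1205.48
#>   component 1: weight 0.444, mean 0.926 Hz, sd 0.137 Hz
#>   component 2: weight 0.556, mean 1.902 Hz, sd 0.435 Hz
#>   crossing frequency f* = 1.212 Hz

res$decayFits$slow
#> DecayFit (decay): % = 389 * exp(-1.58 t), r = 1.584, R^2 = 0.9997

res$connectivity
#> PhaseConnectivity: 6 phase points, 1000 permutations, p = 0.01
#>   phase a (-3.14 rad): threshold 0.321, 164 significant pair(s), GCI = 140.909
#>   phase b (-2.36 rad): threshold 0.319, 168 significant pair(s), GCI = 147.271
#>   phase c (-1.57 rad): threshold 0.323, 166 significant pair(s), GCI = 147.236
#>   phase d (-0.79 rad): threshold 0.315, 166 significant pair(s), GCI = 143.038
#>   phase e (+0.00 rad): threshold 0.321, 158 significant pair(s), GCI = 137.671
#>   phase f (+0.79 rad): threshold 0.317, 156 significant pair(s), GCI = 128.669
```

Reading the output: the mixture recovers the two planted transition-
frequency modes (generator: 0.91 and 1.79 Hz) with the boundary f\* at
1.21 Hz, and 46.8% of waves are labeled slow switchers. The per-class
percentages across the three cycles decline exponentially (the fitted
rates scatter around the generator's r = 1.3/1.6 with a one-night event
count). Because every planted wave propagates across channels with a
constant lag, nearly all of the 171 electrode pairs carry significant
phase-lagged connectivity at every wave phase, and the GCI tracks the
summed |PLI|. The note that AIC proposes more than two components on the
detected inventory is expected — f<sub>τ</sub> of the detected waves is
skewed, and AIC is liberal — while the two-component fit is what defines
the classification; see the methods vignette. `switcher-run/` contains
the per-event tables (`slow_waves.csv`, `spindles.csv`), the mixture and
decay parameters (JSON), the connectivity edge list and GCI table, and a
run manifest.

The same pipeline runs on recorded data from files:

```r
runPipeline(runConfig(input = "files", edfPath = "night.edf",
                      hypnogramPath = "night.csv", outDir = "out"))
```

with the hypnogram either one stage label (W/N1/N2/N3/R) per 30-s epoch
per line, or CSV with columns `epoch,stage,cycle,artifact`.

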