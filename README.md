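# lfpkit

Analysis of hippocampal and prefrontal local field potential (LFP)
recordings from freely behaving rodents, built around the question of how
hippocampal network states — low-gamma oscillations during locomotion and
sharp-wave ripples during immobility — change under experimental
manipulation of a driving circuit (e.g. chemogenetic activation or
silencing of an upstream subfield).

The package is aimed at systems-neuroscience users who record continuous
LFP (≈1 kHz) together with animal position tracking (≈30 Hz) and need a
reproducible, scriptable pipeline from raw traces to per-session summary
metrics. Everything is tidyverse-native: functions take data frames and
return tibbles, results carry `tidy()`/`glance()` methods, and each result
type has an `autoplot()`.

## What it computes

For each session, restricted to a configurable analysis window:

- **Behavioral state segmentation.** Running speed from smoothed position
  (central differences); *run* = speed ≥ 7 cm/s, *rest* = speed < 0.5 cm/s,
  with each rest bout analyzed for at most its first 20 s.
- **Per-state z-scoring** of the LFP, so spectral measures are in
  comparable arbitrary units across recordings.
- **Multitaper spectral power** with 5 DPSS tapers (time–bandwidth
  NW = 3), 2-s windows, 50% overlap, duration-weighted across bouts;
  peak power in theta (5–10 Hz), low-gamma (30–60 Hz) and high-gamma
  (65–100 Hz).
- **Theta–gamma coupling.** The entropy-based modulation index over 18
  theta-phase bins: MI = (log N − H(P)) / log N, where P is the normalized
  mean 30–55 Hz amplitude per phase bin, plus the preferred phase and a
  circular-shift surrogate significance floor.
- **Inter-areal synchrony.** Multitaper coherence |S\_xy| / √(S\_xx S\_yy)
  between hippocampal and prefrontal channels, mean coherence over
  30–60 Hz, and the analytic-signal phase lag with v-tests against 0 and
  2π — the control that separates lagged oscillation sharing from volume
  conduction.
- **Sharp-wave ripples.** 60/180 Hz notch → 69-order zero-phase FIR
  band-pass 100–300 Hz → Hilbert envelope → 50-ms smoothing; events are
  envelope excursions above mean + 3 SD lasting > 30 ms, with a 200-ms
  exclusion after each accepted event; reported as rate (Hz) and envelope
  amplitude (SD units).
- **Unit classification.** Putative pyramidal cells (spike width > 300 µs,
  baseline rate < 5 Hz, autocorrelogram burst peak ≤ 10 ms) versus
  interneurons.

A ground-truthed synthetic session generator (`simulate_session()`)
produces two-channel LFP + position data with all of the structure above —
state-gated theta, theta-phase-coupled low-gamma, rest-only Poisson
ripples, 1/f background, line noise, and a lagged shared gamma component —
so every stage can be validated without animal data.

## Worked example

```r
library(lfpkit)

ses <- simulate_session(sim_params(duration_s = 120), seed = 1)
res <- analyze_simulated(ses, seed = 1, mi_surrogates = 200)
res
#> Session result (window 0-120 s)
#>   run 56.3 s, rest 48.9 s, 46.9% time running
#>   peak powers (a.u.):
#>     run  theta      0.2543 at 7.0 Hz
#>     run  lowgamma   0.006029 at 41.5 Hz
#>     run  highgamma  0.002964 at 80.0 Hz
#>     rest theta      0.07644 at 6.5 Hz
#>     rest lowgamma   0.0148 at 42.0 Hz
#>     rest highgamma  0.002688 at 80.5 Hz
#>   coupling: MI = 0.006226, preferred phase = 94.3 deg
#>   low-gamma coherence = 0.205, phase lag = 1.320 rad
#>   ripples: 0.327 Hz (16 events in 48.9 s), mean amplitude 7.61 SD
```

Reading the output against the generator's ground truth: the run-state
spectrum peaks at the simulated 7 Hz theta and 42 Hz low-gamma; the
preferred coupling phase (94°) recovers the generator's 90° setting, and
the MI (0.0062) exceeds its 95% surrogate floor (0.0028), so the coupling
is detected; the 1.32 rad low-gamma phase lag matches the simulated 5-ms
inter-areal delay (2π · 42 · 0.005 ≈ 1.32) — high coherence *with* nonzero
lag, i.e. not volume conduction; and the ripple rate (0.33 Hz) recovers
the simulated 0.3 Hz rest-state event rate.

Paired-condition comparisons use `simulate_condition_pair()` /
`compare_conditions()`, which report per-metric treated/vehicle ratios —
e.g. a low-gamma amplitude gain of 1.5 appears as a ≈2.25× power ratio.

A small command-line wrapper is installed under
`inst/cli/lfpkit.R` (`simulate`, `segment`, `analyze` subcommands).

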