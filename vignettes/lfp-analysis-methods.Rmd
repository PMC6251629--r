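---
title: "Methods: state-resolved LFP analysis with lfpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-resolved LFP analysis with lfpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpkit)
```

## Overview

`lfpkit` analyzes continuous hippocampal (and optionally prefrontal)
local field potentials together with position tracking, producing
per-session, per-behavioral-state summaries: peak band powers,
theta–gamma phase-amplitude coupling, inter-areal coherence and phase
lag, and sharp-wave ripple statistics. The pipeline is designed for
within-animal treatment comparisons (e.g. vehicle vs. a chemogenetic
ligand), so its outputs are effect sizes — ratios and differences between
paired sessions — not hypothesis tests. Group-level inference is left to
the user, deliberately: with typical cohort sizes of a handful of
animals, the choice of test belongs with the experimental design, not
the signal pipeline.

## Behavioral state segmentation

Position (nominally 30 Hz) is smoothed with a 0.5-s centered moving
average before differentiation; running speed is the Euclidean norm of
central finite differences (one-sided at the edges). Samples at or above
7 cm/s are *running*, samples below 0.5 cm/s are *resting*, and
intermediate speeds belong to neither state. Maximal same-state
stretches of at least 1 s become segments.

Two reading choices deserve note. First, the tie at exactly 7 cm/s
counts as running: the inclusive reading is self-consistent and the
measure-zero boundary is immaterial in practice. Second, the 20-s
immobility rule is read as *truncation*: each rest bout contributes only
its first 20 s of data, rather than long bouts being discarded
altogether. Truncation maximizes usable rest data while still capping
the contribution of any single immobility period (during which the
animal may drift toward sleep); the cap does not restart if the animal
twitches briefly, because sub-threshold movement that never reaches
7 cm/s does not end the bout.

All intervals are half-open `[start, end)` in seconds. Segment edges
are mapped to LFP sample indices by rounding inward, so a segment never
claims samples outside its interval.

## Signal conditioning

Within the analysis window, the LFP samples belonging to each state are
z-scored as one concatenated subset, using that subset's own mean and
population SD. This puts spectra in arbitrary units but makes sessions
recorded days apart comparable, at the cost that *relative* band
composition — not absolute voltage — is what all downstream power
numbers mean. Z-scoring precedes filtering.

Band filters are 4th-order Butterworth band-passes applied
forward–backward (zero phase, effective 8th order). Two numerical
choices matter here:

- The filter is applied as a cascade of second-order sections (biquads)
  rather than in direct form. A 5–10 Hz band-pass at 1 kHz sampling has
  poles so close to the unit circle that direct-form filtering loses
  ~10 significant digits; the biquad cascade keeps linearity and
  time-reversal symmetry at machine precision (both are tested at
  1e-9).
- Before filtering, the signal is padded by odd reflection, with the pad
  length chosen from the slowest pole's decay so start-up transients
  fall below 1e-13 within the pad. Bouts shorter than the pad are
  padded to their own length.

Line noise is removed with constant-Q biquad notches at 60 and 180 Hz
(Q = 30, a common default; the notch bandwidth is not otherwise
constrained by the analysis), also applied zero-phase. Envelope and
instantaneous phase come from the FFT-based analytic signal; the first
and last 100 ms of every bout are flagged edge-invalid and excluded from
all statistics. Phase 0 sits at the positive peak of the band-filtered
oscillation.

## Multitaper spectra

Power spectra use 5 discrete prolate spheroidal (Slepian) tapers. With
the taper count K fixed at 5, the time–bandwidth product follows the
standard convention NW = (K + 1)/2 = 3, giving a ±1.5 Hz analysis
bandwidth on the default 2-s window. Windows overlap 50% within bouts;
bouts shorter than one window but at least 1 s long are analyzed whole,
with tapers re-fit to their length (lengths are quantized to 0.25-s
steps so taper sets can be cached; the discarded remainder is at most
0.25 s per bout). Spectra from different window lengths are interpolated
onto the 0.5 Hz reference grid and averaged weighted by duration. The
estimate is one-sided and normalized so its integral equals the signal
variance (verified by a Parseval test against a plain periodogram).

Tapers are computed from the symmetric tridiagonal matrix that commutes
with the concentration operator — the standard stable construction —
and match `scipy.signal.windows.dpss` to 1e-10 (frozen oracle values in
the test suite).

Spectra are smoothed with a 1-Hz moving average before the *peak* power
in each band is extracted (theta 5–10, low-gamma 30–60, high-gamma
65–100 Hz). Peak rather than mean power is the headline scalar;
band-integrated power is also available (`band_power()`) as a
robustness check. The smoothing kernel and windowing scheme are package
defaults, exposed as arguments.

## Theta–gamma coupling

Coupling between theta phase and low-gamma amplitude uses the
entropy-based modulation index. The mean 30–55 Hz envelope is collected
in 18 theta-phase bins of 20°, normalized to a distribution P, and

MI = (log N − H(P)) / log N,

with H the Shannon entropy in natural log. MI is 0 exactly when P is
uniform and 1 when all amplitude concentrates in one bin. The preferred
phase is the circular mean of bin centers weighted by P. Note the
narrower gamma band here (30–55 Hz) than in the power analysis
(30–60 Hz); both are named constants (`lfp_bands()`).

Because a single MI value has no intrinsic scale, significance is
assessed against circular-shift surrogates: the envelope is rotated by a
uniform random offset of at least one theta cycle, MI is recomputed
(default 200 surrogates), and the 95th percentile is the floor an
observed MI must clear. Shifting preserves both marginal distributions
and autocorrelations while destroying the phase–amplitude alignment,
which is exactly the null of interest. Bin count, entropy base and the
surrogate scheme are all package decisions (the conventional ones);
they are stated here because the index's absolute value depends on
them — comparisons should only ever be made within one configuration.

## Coherence and phase lag

Inter-areal coherence is multitaper: per window and taper, the
cross-spectrum and auto-spectra are accumulated, and coherence is
|S_xy| / √(S_xx S_yy), averaged over at least two (typically dozens of)
non-overlapping 2-s windows collected across run bouts. The headline
scalar is mean coherence over 30–60 Hz.

Phase lag between the two band-filtered signals is computed from
analytic-signal phases rather than wavelet convolution — one consistent
phase definition across the coupling, ripple and synchrony stages. The
per-sample wrapped phase difference is decimated to about one sample per
band-center cycle (≈45 Hz → every 22 ms) to blunt the serial dependence
of neighboring samples, then summarized by the circular mean, resultant
length R, and v-tests for concentration at 0 and at 2π (both run; the
targets are congruent, and reporting both mirrors the convention of
stating the test against each nominal direction). The scientific use is
the volume-conduction control: a genuinely shared oscillation with a
conduction delay shows high coherence *and* a nonzero lag, while volume
conduction would put the lag at zero. The decimated sample count is an
approximation to the effective degrees of freedom; it errs conservative
relative to per-sample counting but is still optimistic if coherence is
very high — another reason the lag estimate, not the p-value, is the
quantity to interpret.

## Ripple detection

During rest, the z-scored pyramidal-layer LFP is notched (60/180 Hz),
band-passed 100–300 Hz with a 69-order FIR filter applied zero-phase,
Hilbert-transformed, and the envelope smoothed with a centered 50-ms
window. The detection threshold — envelope mean + 3 SD — is computed
once over all analyzed rest samples of the session rather than per
bout: "the mean amplitude" is a session-level quantity, and a pooled
threshold is far more stable on short bouts. Supra-threshold runs
longer than 30 ms become candidates; a candidate beginning within
200 ms of the previous accepted event's offset is discarded
(offset-to-onset is the reading adopted; alternatives differ only for
long events), and candidates touching a bout's 100-ms edge-invalid
margins are dropped rather than clipped. Event amplitude is the peak
smoothed-envelope value in SD units above the mean — one of several
defensible amplitude definitions (raw band-passed peak-to-trough and
envelope integral being others); the envelope peak is the one that
directly matches the thresholding statistic.

At least 10 s of rest data are required; below that the threshold
estimate is too unstable to be meaningful.

## The synthetic session generator

`simulate_session()` produces the data the pipeline assumes:

- a run/rest Markov chain at 30 Hz with geometric dwell times, a 2-s
  minimum dwell (mice do not alternate states every 100 ms), and means
  of ~17 s (run) / ~14 s (rest); the trajectory moves at 10 cm/s along
  a smoothly wandering heading that steers away from the 80 × 80 cm
  arena walls, and jitters at 0.2 cm/s during rest;
- 1/f background (spectrally shaped white noise, flat below 1 Hz,
  SD 0.5) plus 60/180 Hz line components;
- theta at 7 Hz, amplitude 1 during run and 0.3 during rest, with
  100-ms cosine ramps at state boundaries;
- low-gamma at 42 Hz whose instantaneous amplitude is
  A₀·g·(1 − κ/2 + (κ/2)·cos(φ − φ₀)) with A₀ = 0.25, coupling depth
  κ = 0.8, preferred phase φ₀ = π/2, and condition gain g — theta phase
  φ taken analytically from the generating oscillator, so coupling
  ground truth is exact;
- high-gamma at 80 Hz (amplitude halved during rest);
- rest-only ripple bursts: Gaussian-windowed 150 Hz sinusoids of 60 ms,
  with onsets from a hard-core renewal process (260-ms dead time,
  exponential gaps rate-compensated so the realized mean rate equals
  the nominal `ripple_rate_hz`), kept 200 ms clear of bout edges;
  burst amplitude is parameterized in units of the rest-state
  ripple-band background SD (default 6 SD) so the detector's operating
  point is controllable;
- a prefrontal channel sharing the low-gamma component delayed by 5 ms
  over independent 1/f noise.

Condition pairs share the locomotion chain (same state seed) and draw
independent noise, differing only in the gain g and the ripple rate —
the isolation that a within-animal design provides.

What the generator does **not** emulate: spike contamination,
electrode drift and movement artifacts, non-sinusoidal theta waveform
asymmetry, state transitions with hysteresis, sharp-wave (low-frequency)
components accompanying ripples, and any pharmacokinetics of a
treatment. Passing tests on synthetic sessions therefore demonstrates
that the estimators recover the structure they target at realistic
SNR — not that real recordings are free of the artifacts above. On real
data, artifact screening should precede this pipeline.

## Validation problem sizes

The test suite and the acceptance script validate on: 120 s of white
noise for spectral calibration; 60–120 s single-state sessions for
coupling and ripple operating points (≈30 injected events per session);
300-s sessions for segmentation recovery; and three 600-s condition
pairs (pooled) for end-to-end gain/rate recovery, where the expected
low-gamma power ratio for a gain of 1.5 is 2.25 and the expected ripple
rate ratio is 0.5. These sizes give each stochastic check comfortable
statistical margin while keeping the full validation run to a few
minutes.

Two small biases are worth knowing about when interpreting the
end-to-end power ratio: z-scoring divides by total signal SD, which
itself rises slightly with the gamma gain (≈2% here), and the 1/f
background beneath the 42 Hz peak dilutes the peak-power ratio toward
1 (≈8% at the default SNR). Both push the recovered ratio from 2.25
toward ≈2.0 — a property of peak-power-over-background estimation, not
an error; band-power on a quiet background recovers g² to within a few
percent (see the spectral tests).

## Known limitations

- The v-test's sample count after decimation still overstates the
  effective degrees of freedom when band coherence is high.
- The MI's absolute value depends on bin count and entropy base; only
  within-configuration comparisons are meaningful.
- Peak-power ratios are diluted by broadband background underneath the
  band peak (quantified above).
- The ripple amplitude definition (envelope peak in SD units) tracks
  but does not equal raw peak-to-trough amplitude.
- EDF/NWB acquisition formats are not read natively; convert to the
  package's CSV/binary signal formats first.
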