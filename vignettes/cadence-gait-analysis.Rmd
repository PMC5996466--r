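---
title: "Cadence-controlled gait analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cadence-controlled gait analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadgait)
```

## The measurement model

A foot-worn triaxial accelerometer sampled at 120 Hz with a ±16 g full
scale measures, on its longitudinal (x) axis, a stereotyped waveform every
gait cycle. Measured from one toe off (TO) to the next, the cycle divides
into a swing phase (canonically 40%) ending at initial contact (IC) and a
stance phase (60%) from IC to the next TO. The segmentation-relevant
landmarks on x are a peak at TO, a deep valley (V-IC) immediately before
IC, a rising zero crossing at IC, and a peak (IC-P) just after IC. The
lateral (y) axis oscillates at step frequency with amplitude reflecting
body sway; the vertical (z) axis is dominated by personal habit and is not
analysed. Seven within-cycle periods are delimited by the events
TO → FA (feet adjacent) → TV (tibia vertical) → IC → OTO (opposite toe
off) → HR (heel rise) → OIC (opposite initial contact) → next TO, giving
initial swing, midswing, terminal swing, loading response, midstance,
terminal stance and preswing.

All sample indices in the package are 0-based and absolute (relative to
the recording origin); a trimmed trace keeps the number of removed samples
in `t0_offset`, so indices from the two feet and from annotation streams
stay directly comparable after synchronisation.

## The synthetic-data generator

No public recordings accompany this kind of protocol, so the generator is
a first-class, tested component that emulates the acquisition conditions:
120 Hz, ±16 g, a 10 s standing-still lead used for synchronisation, walk
types `Normal`, `NC_80/100/120` and `C_80/100/120` (no-cue and cued music
tempos of 80/100/120 BPM), and a two-step stride of
`round(60/cadence · 2 · 120)` samples.

Each cycle's x-axis signal is a fixed template of Gaussian bumps anchored
at the event fractions: TO (+0.55 of the amplitude scale), FA (+0.25), TV
(−0.30), V-IC (−1) and IC-P (+1), with bump width 0.03 of the cycle.
Because the V-IC trough and IC-P peak have equal magnitude and sit
symmetrically ±0.04 cycles around IC, the rising zero crossing falls
exactly at the planted IC sample. This guarantees the landmark *topology*
of real traces without claiming biomechanical fidelity of the waveform
shape between landmarks — the analytic shape of real gait accelerations is
not characterised, and the template is deliberately a stand-in with the
correct landmarks. Consequences for interpretation: passing tests show the
*algorithms* recover what the model plants under realistic noise, sampling
and asymmetry; they cannot show robustness to waveform idiosyncrasies real
sensors produce (double bumps, drift, steps on stairs, pathological gait),
none of which the generator emulates.

Default parameter choices, and why:

* `amplitude_g = 2` — typical peak longitudinal foot acceleration for
  ground walking, comfortably inside the ±16 g range.
* `noise_sd_g = 0.05` (default), `0.1` in the standard noisy cohort — 5%
  of the amplitude, a conservative sensor/soft-tissue noise level. The
  still lead is clamped to ±3 standard deviations, reflecting bounded
  sensor-at-rest noise and giving the documented "near-zero" lead.
* `stance_fraction = 0.60` with period split 13:14:13 (swing) and
  10:20:20:10 (stance) — the canonical textbook fractions; they place OTO
  at exactly 50% of the cycle, so the feet alternate half a cycle apart.
* Cadences: cued walks run at the played tempo; `Normal`/no-cue walks at
  the participant's natural cadence (110 BPM mean, 2% relative s.d.) —
  no-cue tempos are ignored by construction, mirroring the protocol's
  intent.
* Per-participant profiles jitter the within-phase period composition
  (log-scale s.d. 0.08), stance fraction (s.d. 0.01), amplitude (log s.d.
  0.10). Terminal swing is kept above `vic_offset + 2.5·σ` (≈ 11.5% of the
  cycle): observed human terminal-swing shares stay above ~12%, and below
  that bound the TV dip would physically merge into the V-IC descent.
* The jitter preserves `midstance + terminal stance = swing`, which is the
  consistency condition forced by strict half-stride alternation (both
  feet share the cycle length, so opposite-foot events are fixed by the
  inter-foot offset). Published per-foot period tables violate this by a
  couple of percentage points — rounded, empirically asymmetric means need
  not be jointly realizable — so generative profiles derived from them are
  symmetrised first (see `tests/testthat/helper-cadgait.R`).
* Sway factors per walk type (cued-80 lowest, cued-120 highest) plant the
  finding that cued fast walking sways most; `cadence_effect` plants
  linear per-BPM scalings of chosen landmark amplitudes with a known sign
  so correlation recovery can be tested against generative truth.

## Numerical choices in the analysis chain

* **Filter**: Butterworth low-pass at 20 Hz — gait energy lies well below
  20 Hz while sensor noise is broadband. The order (4) and the zero-phase
  forward–backward application are deliberate: timing fidelity is the
  entire point of segmentation, and zero-phase filtering leaves clean
  landmarks within 1 sample of their unfiltered positions. Traces are
  extended by odd reflection (60 samples) before filtering so edge
  transients cannot corrupt the still lead used for synchronisation.
* **Origin detection**: trailing moving RMS (0.25 s window) of mean x/y
  per-axis power against a 0.1 g threshold. A trailing window reacts up to
  one window early, so the qualifying still run is `min_still_s` minus one
  window. Filter first on noisy recordings. Degenerate inputs are
  distinguished: a trace that walks immediately reports "no leading
  clearance", an entirely still trace "no walking segment".
* **Valley threshold**: `T = mean − 0.5·(mean − min)`, computed per trace.
  A per-window variant was considered and rejected for the default path:
  per-trace statistics are deterministic, explainable and sufficient for
  level walking; non-stationary recordings should be windowed upstream.
  Valleys closer than half a nominal cycle merge, keeping the deeper one
  (ties: earlier); the nominal cycle comes from the configured cadence or,
  unknown, the median inter-valley gap.
* **Zero crossing**: the first non-negative sample after the valley — no
  sub-sample interpolation, keeping indices exact sample positions; the
  discretisation bias is under one sample.
* **Toe-off search**: highest local maximum in `IC + (60% ± 5%)` of the
  cycle, ties broken by the earlier sample; the window widens once to
  ±10% before the cycle is dropped. Dropped cycles (undetected IC or TO)
  are excluded from every aggregate and counted in the QC report.
* **FA/TV windows**: centred at the canonical event fractions measured
  from TO (FA 0.13, TV 0.27; half-width 0.05), configurable. Prominence is
  measured as deviation from the window chord: identical to the most
  prominent local extremum for a clear peak, and still resolving the TV
  dip where it rides the monotone descent into the V-IC trough (a strict
  local-extremum rule misses it there). The TV window is clipped on the
  right (0.6 of the half-width) so the chord endpoint stays off that
  descent. A flat window carries no feature and flags the event missing.
* **Heel rise** is never detected from the signal — it has no reliable
  signal feature — and enters only via annotation events; without it,
  midstance and terminal stance are reported merged and flagged.
* **Correlation values**: Pearson's coefficient is computed from the raw
  sums, with constant series returned as missing (never 0). Band
  boundaries at exactly 0.4/0.7 fall in the upper band (the conventional
  overlapping interval notation), and |r| = 1 is reported as "totally
  correlated". Tables pool cycles across participants (the per-participant
  averaging unit is available as an option); a characteristic's value is
  the magnitude of the filtered x acceleration at the event sample
  ("motion strength"), with event timing as the alternative mode — the
  choice of amplitude reflects that cadence effects express themselves as
  motion strength at the landmarks.
* **Quartiles**: linear interpolation (type 7), the fixed common
  convention, for sway box-plot summaries.
* Modulus-maxima wavelet analysis is sometimes mentioned as an aid for
  locating separation positions in this kind of pipeline; it is not
  implemented here — the threshold-line valley detector is the documented,
  tested default and the package takes it as the sole segmentation path.

## Problem sizes

The test suite and the acceptance script use desk-scale cohorts chosen as
the package's standard study conditions: single walks of ~15–25 cycles for
landmark-accuracy checks; the standard cohort of 10 participants × ~20
cycles at 100 BPM (noise 5% of amplitude) for phase recovery; 10–15
records across three cue cadences (≥ 500 pooled cycles) for correlation
recovery; parameter recovery at 10 participants × 21 cycles. Every
simulation is seeded, and the pipeline records the seed in its manifest so
any bundle is reproducible byte for byte.

## Known limitations

* The waveform between landmarks is schematic; amplitude-based
  correlations on real data may behave differently from the planted
  linear effects.
* The generator enforces strict half-stride alternation, so it cannot
  represent strongly asymmetric or pathological gait; left–right
  differences it produces are small by construction.
* Segmentation assumes level, steady walking with one V-IC valley per
  cycle; turning, stair climbing and shuffling violate the template.
* The leading-clearance mechanism requires a genuine still lead of at
  least the configured duration; recordings that begin mid-walk must be
  synchronised externally.
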