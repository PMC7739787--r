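---
title: "Methods: joint kinematics of alpine ski turns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint kinematics of alpine ski turns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skikin)
```

## The measurement problem

During a ski turn the knee extensors mostly resist gravity and the
centripetal load: knee flexion is taken as eccentric work, extension as
concentric work. Classical analyses split each half-cycle in two at the
angle extrema, which hides a third regime that modern carving makes
prominent: long stretches where the joint angle barely moves. This package
implements a velocity-threshold tripartition — samples with angular velocity
in the closed window ±20 °/s are *quasi-isometric* (ISO), flexion faster
than −20 °/s is *eccentric* (ECC), extension faster than +20 °/s is
*concentric* (CON) — and computes, per half-cycle and leg, the absolute and
relative phase durations, the angle extrema, and the mean/max velocity
magnitudes per mode, under both the tripartition and the legacy extrema
bipartition. A mixed linear model then tests how those metrics depend on
discipline (SL, GS, SG, DH), on the inside/outside role of the instrumented
leg, and on their interaction.

Angle convention, used everywhere: degrees of joint extension, larger = more
extended; full knee extension ≈ 180°, so the loaded outside leg sits near
127–132° and the flexed inside leg near 58–67°.

## Filtering

Joint-angle signals have discipline natural frequencies of 0.21–0.54 Hz;
ski/slope vibration sits above 2 Hz. The standard filter is a 4th-order
Butterworth low-pass at 1 Hz applied forward and backward (`zero_phase`), so
the effective magnitude is |H|² with exactly zero phase — no temporal
distortion of the phase boundaries that the ±20 °/s classifier will read
off. Attenuation figures are characterized from the *single-pass* transfer
function, the conventional way selectivity is reported: −3.01 dB at 1 Hz,
93.8 % amplitude reduction at 2 Hz (≈ −24 dB; the often-quoted pairing
"24.5 dB / 94 %" is internally inconsistent by 0.4 dB — the percentage is
what this package asserts), and a −80 dB/decade roll-off (20·order).

Numerical choices: coefficients come from the bilinear transform with
frequency pre-warping; filtering is run as a vectorized direct-form
recursion; edges are handled by odd-reflection padding whose length is
computed from the slowest filter pole so start-up transients decay below
1e−9 before real samples are touched. Inputs with missing samples are
rejected — the pipeline linearly interpolates missing values *only* to keep
the recursion defined, and every cycle containing an originally missing
sample is excluded from the metrics.

`spectrum_report()` gives the one-sided amplitude spectral density with a
Parseval-consistent normalization (`sum(asd²)·Δf` equals the detrended mean
square) and locates the natural frequency as the ASD peak above a 0.05 Hz
floor (below which drift lives; real natural frequencies are ≥ 0.21 Hz).

## Turn segmentation

The resultant trunk acceleration AccR = √(x²+y²+z²) dips when the skier is
unloaded at the edge change. `detect_turn_switches()` filters AccR with the
standard 1 Hz zero-phase filter and takes strict local minima
(negative-to-positive sign changes of the first difference), keeping minima
with prominence ≥ 0.1 g and enforcing a minimum separation (default: a
two-pass bootstrap — 0.3 s first, then 0.4× the median half-cycle spacing —
keeping the deeper of two close minima). The prominence floor was raised
from an initial 0.05 g after measurement: 1 Hz-filtered accelerometer noise
can carve artifact dips of up to ~0.06 g prominence on the long
quasi-static segments of SG/DH runs, while genuine unweighting minima stay
above ~0.15 g. Both knobs are CLI-tunable.

Half-cycles are the spans between consecutive switches. The inside/outside
role of the instrumented (right) leg is not annotated in the raw data; it is
inferred from the angle signal: half-cycles whose mean knee angle exceeds
the run median are provisionally OL (extended = outside), and a single
run-level alternation phase is chosen by majority vote — legs must
alternate, and a global decision is robust to individual noisy segments. A
tie falls back to "first segment OL" with a low-confidence flag in the
segment attributes.

Exclusions mirror field practice: the first and last full cycle (push-off
and finish; maximal acceleration is not reached right after the start gate),
any segment overlapping an annotated course figure (double/triple gates,
banana, jumps), and any segment containing missing samples. A "cycle" is a
consecutive IL+OL pair, so trimming removes two half-cycles at each end.
`time_normalize()` linearly interpolates a segment onto 101 points (0–100 %
inclusive, unambiguous endpoints).

## Phase metrics

Angular velocity is computed by central differences (second-order accurate,
zero phase — a one-sided difference would shift every classifier boundary by
half a sample). The ±20 °/s window is closed: ω = ±20 exactly is ISO, with
strict inequalities bounding ECC/CON. The tripartite mean velocities are
means of |ω| over each mode's own samples, so ECC/CON means exclude the slow
ISO samples; the bipartite means cover all samples of each extrema-defined
phase. That difference is the point: on plateau-bearing signals the legacy
partition dilutes the dynamic means with near-zero samples, underestimating
the true dynamic contraction velocity — the package's tests assert the
tripartite dynamic means exceed the bipartite ones on every simulated
plateau-bearing discipline. The hip uses the same threshold and conventions
as the knee. Per-cycle metrics are computed first and aggregated afterwards
(the alternative — pooling samples across cycles — weights long cycles more;
the per-cycle route matches how repeated-measures models consume the data).

Degenerate inputs: a constant segment is 100 % ISO, has no extrema, and its
bipartite row is flagged `bi_degenerate` (all-CON by convention); empty
modes get zero duration and `NA` velocities, never zeros.

## Density maps

`density_grid()` pools (angle, velocity) samples of retained cycles per
(leg, discipline) into a fixed-edge 2D histogram (defaults 30–180° × 2.5°
and ±200 °/s × 5 °/s — bin widths are a display choice, CLI-tunable).
Out-of-range samples are clipped into edge bins and counted in a clip
report, so total counts always equal the number of samples. Normalization is
a linear division by the grid maximum (idempotent; all-zero grids stay
zero), and rendering uses a linear blue→red map, one panel per grid.

## Mixed-model statistics

Repeated cycles within a skier-session (skier × day × discipline) violate
independence, designs are unbalanced, and cycles go missing after cleaning —
exactly the setting for a random-intercept model,
`Y ~ Discipline * Leg + (1 | session)`, fitted by REML with lme4. Angle
extrema are a special case: the maximum comes from OL and the minimum from
IL, so those responses use the reduced `Y ~ Discipline + (1 | session)`.

Because the usual companions (`lmerTest`, `emmeans`) are not available in
the build environment, the package computes inference itself, exploiting the
closed form of the random-intercept covariance (V is block diagonal with
V_j = σ²I + τ²J, so inverses, determinants and the REML criterion are exact
and cheap):

* **Satterthwaite degrees of freedom** for a contrast c′β:
  df = 2g²/(∇g′ A ∇g) with g(θ) = c′ Var(β̂; θ) c, gradient by central
  differences in θ = (τ², σ²), and A = 2H⁻¹ from the finite-difference
  Hessian of the REML −2ℓ. At the τ² = 0 boundary the df fall back to the
  residual N − p (correct in the iid limit). On balanced between-session
  designs the computed df reproduce the exact value (#sessions − #groups)
  to two decimals.
* **Type-III-style F tests** per term from marginal-mean contrast matrices,
  with the denominator df pooled over the eigen-contrasts of L Var(β̂) L′
  (the `2E/(E−q)` pooling).
* **Tukey contrasts**: all pairwise differences of estimated marginal means
  within a family (a factor's margins, or slices such as disciplines within
  each leg), p-adjusted with the studentized range on the contrast's
  Satterthwaite df; with two groups this reduces exactly to the t-test.
* **Effect sizes**: mixed-model Cohen's d = |Δ|/√(τ² + σ²) — the total-SD
  standardizer, invariant to affine rescaling of the response — labelled
  trivial/small/medium/large with closed lower bounds 0.20/0.50/0.80.
* **Log transform**: applied automatically when a Shapiro test (α = 0.01,
  n capped at 500 by a seeded subsample) rejects normality of the
  *within-cell residuals*, all values are positive, and the log scale tests
  no worse. Testing residuals rather than raw values keeps genuine group
  differences from masquerading as non-normality.

A null simulation (400 seeded replicates) keeps the Tukey familywise error
at the nominal level, and the ANOVA p-value of a true-null term passes a
Kolmogorov–Smirnov uniformity check — both run in the test suite.

## The synthetic-run generator

No athlete recordings are deposited, so the generator is a first-class,
tested module that states a world with the structure the analysis assumes:

* **Durations.** Half-cycle ("turn") durations are lognormal with the
  published per-discipline means (SL 0.91, GS 1.47, SG 2.0, DH 2.5 s —
  inside the published mean ± 1 SD envelopes) and cv 0.15–0.22, truncated
  at ±1.25 SD and rescaled to the exact mean. Truncation is a deliberate
  part of the stated world: a gated course imposes a quasi-regular rhythm,
  and — decisively — two switches closer than ~0.7 s are *physically
  unresolvable* after the fixed 1 Hz detection filter (measured two-dip
  resolution limit), so unbounded tails would make perfect detection
  impossible in principle, not just in practice. The first/last two
  half-cycles are 15 % longer and carry a reduced-amplitude envelope
  (push-off and finish), giving the trimming rule something real to
  discard.
* **Angles.** Each half-cycle is a keyframe trajectory: quintic-smoothstep
  rise from the switch angle to the leg's extremum, a flat plateau occupying
  the profile's quasi-isometric fraction, and a symmetric return (a pure
  sinusoid cannot realize discipline-specific ISO fractions). The clean
  angle is this trajectory *projected onto the analysis filter's passband*
  (four passes of the 1 Hz zero-phase filter): the movement signal is
  band-limited by construction — consistent with natural frequencies of
  0.21–0.54 Hz — and the pipeline's own filtering is then effectively
  transparent, so ground truth and measurement refer to the same object.
  Band-limited vibration noise (2–15 Hz, 1.0–1.8° SD) rides on top.
* **Calibration and its limits.** Plateau fractions were calibrated once,
  at design time, against the published outside/inside-leg quasi-isometric
  percentages. The 1 Hz bandwidth caps what fast waveforms can realize:
  SL (0.9 s half-cycles) saturates near 14 % ISO whatever the plateau, and
  the two GS legs couple through filter ringing across the shared switch,
  so the GS targets (34/20) are not jointly reachable. Realized clean-signal
  values: OL ≈ 14/31/42/38 and IL ≈ 15/11/28/38 (SL/GS/SG/DH) against
  published 11/34/42/38 and 19/20/28/38. All published *orderings* — the
  outside-leg discipline ordering, the GS/SG outside-leg ISO dominance, the
  SL reversal, DH symmetry — are preserved, which is what the acceptance
  criteria exercise; absolute Table-level reproduction is explicitly out of
  scope. The SL switch angle (87°) was likewise chosen so that the SL
  reversal is realizable at all under the bandwidth cap.
* **Acceleration.** The trunk carries a sustained load plateau
  (1 + 0.8–1.8 g with one smooth dome per half-cycle) interrupted at every
  edge change by a brief symmetric unweighting dip down to 1 g. Narrow dips
  are localized events whose low-frequency content survives the 1 Hz
  filter, so filtered minima stay deep and centred in all four disciplines —
  a sinusoidal bump train at the SL half-cycle rate (~1.1 Hz) is annihilated
  by the same filter, an instructive dead end. Declared switch times are the
  sub-sample vertices of the minima of the noise-free filtered AccR, and the
  angle schedule is anchored to them, so angle reversals and detectable
  minima coincide exactly; the raw dip centres agree within a sample or two
  (a few tens of ms for SL, where the filter sits on the turn-frequency
  knee). White accelerometer noise (0.08 g) is added per channel.
* **Reproducibility.** One integer seed drives a private RNG stream
  (durations, then knee/hip vibration, then x/y/z noise); the caller's RNG
  state is untouched and equal seeds give bit-identical output.

`simulate_metrics_dataset()` composes whole studies: sessions are allocated
round-robin across disciplines (each session belongs to one discipline, as
in the real skier-day-discipline design), each session perturbs the plateau
fractions (SD 0.03) and mean duration (cv 0.05), and each run goes through
the *full* measurement pipeline before the metrics rows are stacked.

## What a green test establishes — and what it does not

The generator emulates durations, keyframe angle structure, band-limited
spectra, plateau-style quasi-isometry, switch-anchored acceleration minima,
and session-level heterogeneity. It does not emulate: terrain- and
course-induced non-stationarity, asymmetric left/right turns, goniometer
drift or slippage, gate-contact artifacts, or the muscle-level distinction
between joint and fascicle behaviour (a knee-level "eccentric" phase need
not be an eccentric contraction of any particular muscle). Green acceptance
tests therefore establish that the *pipeline* recovers what it is designed
to measure in a world with the stated statistical structure — not that the
published group values would be reproduced from new athlete data.

## Known limitations

* Satterthwaite df are an approximation; at variance-component boundaries
  the code falls back to residual df, which is anti-conservative when the
  true session variance is positive but estimated at zero (shared with the
  standard toolchain).
* The 1 Hz filter both defines and limits the measurement: SL amplitudes
  are attenuated by several percent (the same compromise reported for real
  data) and the quasi-isometric fraction of sub-second half-cycles is
  bandwidth-capped, as quantified above.
* The leg-assignment heuristic assumes the OL/IL angle contrast survives
  filtering; a run consisting entirely of near-symmetric half-cycles would
  be labelled by the tie-break and flagged low-confidence.
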