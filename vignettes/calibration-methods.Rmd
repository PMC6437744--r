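---
title: "Calibrating multipad electrotactile arrays: procedure, model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating multipad electrotactile arrays: procedure, model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etcal)
```

## Why calibrate

An electrotactile feedback interface drives low-level current pulses
through an array of skin electrodes; information is coded by which pad is
active and how it is pulsed. For the code to be readable, a given
"intensity level" must feel the same on every pad — but electrotactile
sensitivity varies systematically around the forearm (the volar side
needs less current than the dorsal side), idiosyncratically between
subjects, and from session to session even within a subject. The
calibration curve — one amplitude per pad, on the device's 0.1 mA grid
between 0.1 and 5 mA — must therefore be re-established at every
electrode donning. This package implements the calibration procedure,
the analyses that quantify the variability, and the streamlined
procedure those analyses justify.

## The procedure

**Phase 1 (method of limits).** For each pad in order, amplitude ramps
from 1 mA upward in 0.1 mA steps until the subject signals a distinct
but pleasant sensation; that amplitude is the pad's baseline
(`run_phase1()`). A ramp that reaches the 5 mA ceiling without a
response is recorded as a flagged non-response with the ceiling value
retained, not an error. A brief fast scan (0.2 s per pad, ascending)
lets the subject review the result.

**Phase 2 (fine-tuning).** Discriminating small intensity differences is
much easier between temporally adjacent stimuli on neighbouring pads
than in isolation. The fine-tune schedule therefore chains triads:
pads (k, k+1, k) for k = 1..n−1, then a closing activation of pad n
(`build_finetune_sequence()`). Each interior pad is felt before and
after each neighbour — exactly 3 activations per interior pad, 2 for
each end pad, 3n − 2 activations in total; with n = 16 and the 2 s
dwell, one pass is 46 activations and 92 s. While a pad is active the
subject clicks it up or down in 0.1 mA steps (`run_finetune()`); passes
repeat until the subject declares the curve even.

The chained-triad order is a reconstruction: the procedure's published
description prints only the fragment 5‑4‑5‑6‑5‑6‑7‑6 and the totals
(46 activations, 92 s, interior pads 3×). The triad chain is the unique
simple construction consistent with all three, and our tests pin each of
those facts. Whether the original ran 1→16 or mirrored is not
determinable from the totals; we fix the ascending orientation. The same
evidence forces *linear* (non-wrapping) adjacency even though the
electrode physically encircles the forearm: under wrap-around adjacency
the end pads would need 3 activations each and the totals would not come
out at 46.

**Streamlined procedure.** Phase 2 only, started from an a-priori
baseline (`run_streamlined_session()`). The default baseline is the
cohort 25th-percentile curve floored to the grid: unlike the mean curve
it almost never exceeds a subject's observed range, so fine-tuning
approaches preferred values from below — preferable both ergonomically
and because higher amplitudes habituate faster. Its theoretical minimum
duration is a single 92 s pass.

## Timing model

Dwells are parameters of `timing_model()`: 2.0 s per fine-tune
activation and 0.2 s per fast-scan pad are the procedure's stated
values. No per-step duration is published for the phase-1 ramp; the
default of 1.0 s per step makes baseline acquisition for typical
preferred amplitudes near 2 mA take 16 × 11 = 176 steps ≈ 3 minutes,
matching the reported experience that reaching the baseline alone took
on the order of three minutes. Clicks are modeled as instantaneous
within an activation dwell, so elapsed time is passes × pass duration;
action counts are tracked separately and exactly.

## Effort metric and baseline candidates

The effort to get from a baseline *b* to a selected curve *c* is the L1
distance Σₚ|bₚ − cₚ| (`total_distance()`), which is 0.1 mA × the click
count — an identity the engine maintains exactly in integer tenths
(`action_distance_identity()`). Three baseline candidates are compared
(`compare_baselines()`): the historical 1 mA constant, the optimal
constant, and the overall mean curve. The optimal constant minimizes the
summed L1 distance over the device grid by exhaustive search
(`optimal_constant()`); since the L1 minimizer over the reals is the
pooled median interval, the search result must and does land within one
grid step of that interval, with ties broken toward the smaller
amplitude. Distances are compared with a one-way repeated-measures
ANOVA using the Greenhouse–Geisser correction plus Bonferroni-adjusted
paired t-tests (`rm_anova_gg()`), treating each session curve as a unit
measured under all candidate baselines.

Numerical conventions, fixed once and used everywhere:

- *Sample SD* (n−1) for every dispersion summary. The published CV
  table's row summaries discriminate the conventions (subject 1:
  ±3.0 printed; 2.99 under n−1, 2.89 under n) and select n−1.
- *Percentiles* interpolate linearly at rank (n−1)q/100 + 1
  (`stats::quantile` type 7); the convention is configurable.
- *Grid arithmetic* is integer tenths of a mA throughout, with a 1e-9
  tolerance only at the float boundary, so grid membership and the
  action-distance identity are exact integer statements.
- *Snapping analysis curves to the grid* uses floor by default (again:
  approach from below); `to_grid(, "nearest")` rounds half away from
  zero.
- Analysis curves (means, percentiles) deliberately stay off-grid;
  they are floored only when they seed an actual stimulation session.

The Greenhouse–Geisser epsilon is computed from the double-centered
condition covariance matrix, ε = tr(Ŝ)² / ((k−1)·ΣŜ²), clamped to
[1/(k−1), 1]; with k = 2 conditions ε = 1 exactly and F equals the
paired t² — both properties are tested, and the whole procedure is
cross-checked against an independent explicit sums-of-squares and
eigenvalue oracle.

## The virtual-subject model

`make_profile()` draws a subject as a true preferred curve

> true(p) = A₀ − A₁·cos(2π(p − center)/n) + offset(p)

oriented so the middle (volar) pads take the lowest amplitudes and the
end pads near the dorsal junction the highest — the convex cross-array
shape reported for forearm electrotactile sensitivity. Per-pad Gaussian
offsets (SD 0.15 mA by default) give each subject a stable fingerprint.
Session-to-session variation is multiplicative: each session's target is
true × (1 + ε) with ε ~ N(0, CV/100) per pad, clamped to the device
range and floored to the grid (`sample_session_target()`). A
multiplicative model is the minimal choice consistent with variability
that is reported as CVs. Response behavior is truthful with a reaction
overshoot of 0–2 ramp steps: the ramp stops at the first amplitude ≥
target + overshoot × 0.1 mA, and fine-tune clicks walk straight to the
target (`make_responder()`).

Default bands, chosen once to make the simulated cohort resemble the
reference cohort and documented here rather than tuned: A₀ ∈ [1.5, 2.5]
mA and A₁ ∈ [0.2, 0.8] mA put cohort medians in the 1.5–2 mA region
(and, empirically, the optimal constant near 1.8 mA); session CV is
drawn uniformly in [13, 27]%, spanning the reference per-subject mean
CVs (13.1–26.6%); the overshoot set {0, 1, 2} yields phase-1 times
around three minutes. An optional per-pad CV multiplier can emulate the
elevated variability of the volar/dorsal transition pads (4–5 and
13–14); it is off by default because the effect is only qualitative.

What the generator does *not* model: afferent recruitment and
habituation dynamics, electrode–skin impedance, placement error between
donnings, amputee-specific factors, or non-monotone click behavior.
Passing tests on simulated cohorts therefore validate the machinery —
schedules, accounting, estimators, tests — not the physiology; claims
about real subjects rest on the published summaries packaged as
fixtures, which the same estimator code reproduces.

## Quantization effects worth knowing about

Flooring session targets to the 0.1 mA grid shifts their expectation
down by about half a step. Parameter-recovery checks therefore compare
the empirical per-pad session mean against the true curve after a
0.05 mA offset, at 3 standard errors; similarly, empirical CV checks
allow one percentage point for grid quantization on top of Monte-Carlo
error. Both corrections follow from the grid geometry, not from fitting.

## Problem sizes and determinism

All simulation-based tests and the acceptance script use fixed seeds and
modest sizes — the 9 × 10 reference cohort shape for cohort-level
properties, 40 sessions for single-subject recovery, 100 random datasets
for the optimal-constant oracle sweep — sizes at which every Monte-Carlo
tolerance above is computed from the realized standard errors. Cohort
simulation, all analyses and the full test suite run in seconds; results
are bit-reproducible given the seed, and `simulate_cohort()` restores
the caller's RNG state.

## Known limitations

- The fine-tune orientation (ascending vs mirrored) is inferred, not
  documented; both give identical totals.
- Real fine-tune pass counts for dissatisfied subjects are free
  parameters of the responder; no published distribution exists to
  calibrate them.
- The improvised "fast mode" correction loop some subjects preferred is
  reported only qualitatively in the literature; the engine exposes the
  fast-scan schedule but does not model that loop's timing.
- `cv_pad_multiplier` is a coarse stand-in for placement-dependent
  transition-zone variability.
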