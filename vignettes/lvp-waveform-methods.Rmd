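---
title: "Methods: left ventricular pressure waveform analysis and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: left ventricular pressure waveform analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

An implantable pressure catheter in the left ventricle of a conscious,
unrestrained animal streams chamber pressure at 500 Hz for days. From that
stream a physiologist wants, per beat, the classical indices of systolic
and diastolic function — heart rate, mean LVP, LVSP, LVEDP, dP/dt~max~,
V~max~, −dP/dt~max~ and the relaxation time constant Tau — and, per study,
their multi-day trends. The raw transmitter reports a frequency that must
first be mapped to absolute pressure via bench calibration and corrected to
gauge pressure against an ambient-pressure reference.

Real telemetry baselines of this kind are rarely deposited, so the package
validates itself against a synthetic generator whose waveforms have
*analytically known* index values: every pipeline stage is tested
end-to-end by asking whether it recovers the numbers the generator was
configured with.

## The beat template

Each beat of length $RR$ is a piecewise-smooth pressure curve with seven
segments (phase $u$ from beat onset):

1. **End-diastolic hold** at `lvedp` for
   $t_1 = \min(10\,\mathrm{ms},\,0.04\,RR)$.
2. **Upstroke**: raised cosine from `lvedp` to `lvsp` over
   $T_r = \pi\,\Delta P / (2\,\dot P^+)$, where $\Delta P =$
   `lvsp − lvedp`. A raised cosine has peak slope
   $\Delta P\,\pi/(2T_r)$ at its midpoint, so the template attains the
   configured dP/dt~max~ $\dot P^+$ exactly, at a known instant.
3. **Systolic plateau** at `lvsp` for $\min(25\,\mathrm{ms},\,0.1\,RR)$ —
   a stand-in for the ejection phase that keeps LVSP well-defined over
   several samples and lifts mean LVP into the physiological range.
4. **Fall**: the first half of a raised cosine; its slope reaches the
   configured $-\dot P^-$ exactly at the half-period point $t_4$, the
   −dP/dt~max~ fiducial.
5. **Relaxation to the Tau target**: from $t_4$ an offset exponential
   $P(u) = C + B e^{-u/\tau_A}$ chosen so that (i) its initial slope is
   $-\dot P^-$ (the waveform is $C^1$ at $t_4$, so the derivative extremum
   is genuine, not a jump) and (ii) it crosses the Tau target pressure
   $P_{tgt} = \mathrm{LVSP} - 0.66(\mathrm{LVSP}-\mathrm{LVEDP})$ exactly
   `tau66_ms` after $t_4$. Writing $\Delta_1$ for the pressure drop from
   $t_4$ to the target and $a$ for `tau66`, the two conditions reduce to
   $(1-e^{-x})/x = \Delta_1/(\dot P^- a)$ with $\tau_A = a/x$, solved by
   bisection; the crossing slope is then $\dot P^- e^{-x}$.
6. **Late relaxation**: exponential toward the configured diastolic floor,
   slope-matched at the crossing.
7. **Refill**: a raised cosine (zero slope at both ends) that lands on
   `lvedp` exactly at the next onset.

Every index therefore has a closed-form location and value, which the
generator emits as ground truth; mean LVP is assembled from the closed-form
segment integrals, and V~max~ from the analytic maximum of the
pressure-normalized upstroke slope.

### Why this relaxation parameterization

A natural alternative is a single exponential decaying to the diastolic
floor with its time constant chosen so the 66% crossing lands at `tau66`
(the closed form implemented in `solve_tau_exp()`, which the package
exports as the analytic inverse and uses throughout its Tau tests). That
shape cannot, however, satisfy the slope constraint at the −dP/dt~max~
point for a large part of the physiological parameter space: combinations
of slow Tau (≈ 50 ms) with large −dP/dt~max~ (≈ 2500–3000 mmHg/s) — which
real rabbits exhibit — would require the decay to start above LVSP for any
admissible floor. The resulting slope discontinuity shifts the discrete
derivative extremum by several samples and corrupts both the −dP/dt~max~
and the Tau read-outs. The slope-matched offset exponential keeps the
corner $C^1$ and the crossing exact, at the cost of an asymptote that is
not the diastolic floor — which is why segment 6 exists.

### The drop budget $\Delta_1$

$\Delta_1$ (how much pressure falls between the corner and the Tau target)
is the one free geometric knob, and it trades three failure modes against
each other:

* too small, and the crossing becomes nearly flat
  (slope $\dot P^- e^{-x} \to 0$), making the measured Tau hypersensitive
  to sub-0.1 mmHg pressure errors;
* too large, and the cosine fall above the corner becomes so brief that
  sampled derivatives cannot read the corner faithfully;
* larger than $\dot P^- \cdot$ `tau66`, and no monotone decay can satisfy
  both constraints at all.

The default is $\Delta_1 = \min\{\max(0.33\,\Delta P,\ \rho_{min}\dot P^-
a),\ 0.7\,\dot P^- a,\ 0.66\,\Delta P - 0.0075\,\dot P^-\}$, where
$\rho_{min}$ is the drop ratio at which the crossing slope would fall to
20 mmHg/s. Parameter combinations violating all constraints at once
(−dP/dt~max~ too large for the available systolic–diastolic span, or a
beat that cannot fit systole plus relaxation inside 85% of the RR
interval) raise an explicit infeasible-geometry error rather than
producing a distorted waveform.

## The simulator around the template

* **RR jitter**: lognormal with configurable coefficient of variation
  (default 0.03 — mild, rabbit-resting-state variability); lognormality
  guarantees positive intervals.
* **Measurement noise**: additive white Gaussian, default 0.5 mmHg
  (fluid-filled catheter systems at 500 Hz are quiet but not noiseless).
  Noise is drawn in fixed 20-s blocks, each block seeded from the config
  seed plus the block index, so streamed chunked rendering reproduces a
  full-run stream bit-for-bit regardless of chunk boundaries.
* **Circadian drift**: a sinusoid (default 2 mmHg amplitude, 24-h period)
  added to the whole signal, standing in for the slow baseline wander of
  multi-day recordings.
* **Ectopic beats** (`inject_artifacts()`): with per-beat probability
  `ectopic_rate`, a beat fires prematurely at 62% of the preceding RR with
  amplitude and slopes attenuated (65% of the pressure span, 75% of the
  slopes), followed by a compensatory pause. This produces the short–long
  RR signature that the QC irregularity rule targets.
* **Wall-contact transients**: a Poisson process (events/hour) of 0.2–2 s
  windows of 25–45 Hz oscillation at 40–80 mmHg amplitude under a smooth
  envelope — the signature of the catheter tip touching the ventricular
  wall.
* **RNG discipline**: RR, ectopic, wall-contact and noise draws use
  separate sub-streams derived from the config seed, so toggling one
  artifact type never shifts another's draws; this is load-bearing for the
  tests that replay individual streams against oracles.

Defaults describe a resting rabbit baseline: 240 bpm, LVSP 107, LVEDP 20,
dP/dt~max~ 3000, −dP/dt~max~ 2500 mmHg/s, Tau66 29 ms — mid-range values
for conscious-rabbit telemetry. The generator's ground-truth tables report
beat onsets at the end-diastolic upstroke foot (the end of the diastolic
hold), since that is the fiducial a dP/dt-anchored detector can see.

### What the generator does *not* emulate

Real LVP waveforms vary in morphology between animals and over time
(catheter position, respiration-coupled modulation, autonomic tone); the
template is one fixed smooth shape per parameter set. Real noise has
colored components (motion, electromagnetic pickup) rather than white;
real arrhythmias are more diverse than single premature beats; drift is
not a clean sinusoid. Passing the recovery suite therefore demonstrates
that the estimators are *correct and tight on waveforms whose true values
are known*, not that they are robust to every failure mode of live
telemetry. The QC layer is the intended guard for the latter, and its
thresholds are deliberately exposed as policy.

## Detection and estimation

**Derivative.** `estimate_derivative()` defaults to the central
difference (the textbook definition of dP/dt from sampled pressure), with
one-sided differences at the edges; a Savitzky–Golay variant (order 3,
11-sample window) and a single-interval backward difference are
selectable. Gaps propagate.

**Beat candidates** are local maxima of dP/dt above
0.3 × (rolling 10-s derivative maximum) — adaptive, so animals with LVSP
anywhere in the 99–114 mmHg spread need no per-animal threshold — with a
150 ms refractory period (a 400 bpm ceiling). **Onset** (end-diastole) is
the last sample below 5% of the beat's own dP/dt~max~ before the upstroke
crosses that level. Five percent rather than ten keeps the onset sample on
the end-diastolic baseline: at 10% the crossing lands one sample into the
upstroke and biases LVEDP by ≈ +0.2 mmHg, which matters because the Tau
target inherits 0.66 of any LVEDP error. **Systolic peak** is the pressure
maximum before the next candidate (earliest sample on ties), −dP/dt~max~
the derivative minimum after it, and a beat's end is the next beat's
onset; all windows are half-open `[start, end)` and sample *i* (1-based)
sits at time $(i-1)/f_s$. Beats spanning gaps, or failing the fiducial
ordering, are dropped and counted. The trailing beat, truncated by the
recording edge, is emitted with an `edge` flag and excluded from RR
irregularity statistics and epoch means.

**Noise-adaptive filtering.** The −dP/dt~max~ point of any waveform that
satisfies the Tau geometry is intrinsically a *narrow* derivative
extremum: the slope must collapse from −dP/dt~max~ toward the mean
relaxation slope $\Delta_1/$`tau66` within a few milliseconds, so the
region where the derivative is within 2% of its extremum spans only
~2–4 ms at rabbit parameters. Two regimes follow at 500 Hz:

* On a *clean* signal, the right estimator is the two-point backward
  difference: its single-interval footprint reads the corner with ≤ 0.5%
  flattening. But its white-noise sd is $\sigma f_s \sqrt 2$ ≈ 700 mmHg/s
  at $\sigma = 1$ mmHg — unusable on noisy data.
* On a *noisy* signal, an 11-sample Savitzky–Golay derivative cuts the
  noise sd to ≈ 48 mmHg/s, but its ±10 ms footprint flattens the corner by
  3–5%. No single linear filter serves both regimes; with 1 mmHg noise at
  500 Hz, per-beat derivative extrema cannot be estimated much better than
  ±100 mmHg/s by *any* estimator, because averaging enough samples to beat
  the noise necessarily spans more than the corner's width.

`analyze_recording()` therefore estimates the noise level first —
`mad(diff(p, differences = 2))/sqrt(6)`, a second-difference MAD that the
smooth physiological signal barely contaminates — and switches at
0.15 mmHg between the raw backward-difference branch and the smoothed
Savitzky–Golay branch. The raw central difference is always used for the
spike-artifact QC check, and the smoothing switch, window and threshold
are pipeline configuration.

**Indices.** LVSP is the window maximum between the dP/dt fiducials;
LVEDP the onset-sample pressure; the dP/dt extrema are the derivative
values at their fiducials; mean LVP the half-open beat-window mean; heart
rate 60/RR. Tau66 is the time from the −dP/dt~max~ fiducial to the first
downward crossing of $P_{tgt}$, linearly interpolated between the
bracketing samples — at 500 Hz the sample spacing alone is 2 ms, and
interpolation makes the estimator smooth in the underlying time constant
("diastolic" in the 66% rule is the same beat's LVEDP, the one
operationalization that is computable per beat and testable). V~max~ is
the peak of $(dP/dt)/\max(P, 1\,\mathrm{mmHg})$ over isovolumic
contraction; when the backward-difference derivative is in use the
denominator is taken at the interval midpoint so numerator and denominator
describe the same instant. Note that with absolute chamber pressure in the
denominator this index is bounded by dP/dt~max~/LVEDP (≈ 10² 1/s);
commercial analysis programs print ~10³ 1/s under the same name, so their
normalization evidently differs and V~max~ values are comparable within,
not across, analysis packages. The formula is stated prominently in the
function documentation for exactly this reason.

## Quality control

Per-beat flags: `irregular` (RR deviating > 25% from the median RR of the
surrounding 30 s), `artifact` (overlapping a pressure-bound excursion,
default 0–250 mmHg gauge, or a derivative spike above 6000 mmHg/s — above
any physiological dP/dt here but below wall-contact slew rates), `edge`,
and gap-related drops. A recording is excluded when the irregular fraction
exceeds 5% or artifact time exceeds 10% — thresholds that reproduce the
practice of discarding a post-surgical arrhythmic baseline outright rather
than averaging over it. All five thresholds are invented defaults, exposed
in `qc_policy()` and echoed in every QC report.

## Aggregation

Beats are assigned by onset time to contiguous half-open 20-s epochs (the
standard telemetry storage granularity); QC-flagged beats are excluded
from epoch means and counted in `artifact_fraction`; empty epochs carry
missing means. The 1-h moving average is trailing (right-aligned), emitted
only for complete windows, with the SEM taken across the non-missing epoch
means inside the window — the convention behind "hourly average with
standard-error bars" displays; missing epochs are excluded, never
zero-filled. Daily summaries partition the recording into 24-h blocks from
the recording start, mean ± SEM per parameter per block, with a partial
trailing day flagged. Two conservation properties are enforced by test:
every valid beat contributes to exactly one epoch and every epoch to one
day, and the epoch-count-weighted mean of daily means equals the grand
epoch mean.

## Problem sizes used in validation

The recovery suite analyzes twenty 10-min noise-free recordings drawn
across the baseline physiological ranges (HR 200–300 bpm, LVSP 99–114,
LVEDP 17–24 mmHg, dP/dt~max~ 2116–4126 mmHg/s, Tau 22–54 ms), recovering
configured values to ≤ 1 bpm, ≤ 0.5 mmHg, ≤ 2% and ≤ 2 ms respectively;
joint parameter draws whose systole plus relaxation cannot fit the RR
interval are rejected as infeasible and redrawn. Structural behavior is
checked on a full simulated 72-h baseline (12,960 epochs, 12,781 hourly
trend points, three daily rows per parameter) streamed in 1-h chunks. The
noise-robustness suite runs the default baseline configuration at
1 mmHg noise and requires median absolute per-beat errors within twice the
noise-free tolerances; at the sharpest corner geometries in the parameter
space that bound is not attainable by any estimator at 500 Hz (see the
error-budget discussion above), which is a property of the
sampling/noise regime, not of a particular implementation.

## Known limitations

* One fixed template morphology; no between-animal waveform variety.
* Tau is the operational 66%-crossing time only; monoexponential
  regression and related estimators are out of scope.
* dP/dt-based indices are load-dependent; no preload/afterload correction
  is attempted.
* The affine calibration form is an assumption (the transmitter's raw
  frequency model is unpublished); the three-point residuals are reported
  as a linearity check rather than silently absorbed.
* Single-channel pressure only; no ECG-assisted detection.
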