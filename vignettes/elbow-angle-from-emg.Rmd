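---
title: "Estimating continuous elbow-joint angle from single-channel surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating continuous elbow-joint angle from single-channel surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgangle)
```

## The problem

A single surface-EMG channel over the biceps brachii carries enough
information to reconstruct the elbow-joint angle during voluntary flexion
and extension in the sagittal plane — the configuration used in bilateral
rehabilitation, where the intact arm's EMG drives an exoskeleton worn on
the impaired arm. The movement visits three contraction regimes: concentric
(flexion), isometric (holding), and active shortening (extension). This
package implements the complete estimation pipeline — EMG conditioning,
muscle-activation dynamics, a Hill-type-model-motivated quadratic
calibration map, and a four-state switching model — together with a
synthetic surface-EMG generator so every stage is testable without human
recordings.

## Model and processing chain

**Mechanics.** With the tendon assumed rigid and triceps/brachialis
contributions neglected, the sagittal-plane torque balance reduces the
biceps musculotendon force to a function of gravity and the inertial term,
`F_B = mgL/l + (I/l)·θ̈·sinθ`. Substituting a Hill-type contractile model
(`F = F_max·a·f_l·f_v`, with the Gaussian force–length factor peaking at a
relative length change of 0.05 and the classic sigmoid force–velocity
factor) and the geometric relations `ΔL_CE = α·L_CE0·cosθ`,
`V_CE/V_CE0 = −0.1·α·θ̇·sinθ`, then taking logarithms and discarding the
small `ln f_v` term (numerically, `f_v` stays within about 12 % of 1 for
`|θ̇| ≤ 90°/s` over the 0–90° range) yields a relation in which `cos²θ` is
a quadratic-like function of scaled activation `a/R`. All lumped constants
(`mgL/l`, `F_max`, the 0.05 offset, `α`, …) are absorbed into three fitted
polynomial coefficients; none is estimated individually.

**Signal chain.** Raw EMG (1000 Hz) is high-pass filtered (4th-order
Butterworth, 10 Hz) to remove offsets and motion artifact, rectified,
passed through the second-order recursive activation-dynamics filter
`u(t) = α·e(t−d) − β1·u(t−1) − β2·u(t−2)` with `β1 = γ1+γ2`,
`β2 = γ1·γ2`, `α = 1+β1+β2` (poles `|γ| < 1` guarantee stability and the
coefficient constraint guarantees unity DC gain, so excitation never
exceeds a bounded input in steady state), low-pass smoothed (2nd-order
Butterworth), normalized by the maximum voluntary contraction (MVC)
envelope peak, and mapped through `a(u) = (e^{u/R} − 1)/(e^{A} − 1)`.
A value-rectification dead band with staircase semantics (changes within
1–3 % of the held value are suppressed; larger changes pass through)
stabilizes the activation before state switching.

**State switching.** A single quadratic map cannot represent the whole
movement: at the flexion→holding transition the activation *overshoots*
(the acceleration torque vanishes when the arm stops) and then relaxes to
the isometric plateau, and during extension the same map would jump.
Four states resolve this: relaxation outputs 0°, flexion outputs the
inverse map `θ = arccos(√(clamped quadratic))`, holding freezes the last
flexion angle, and extension outputs `p·invert_map(a)` with the
proportional continuity gain `p = θ_max/θ′_max` spliced at the exit so the
output has no jump points.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `highpass_hz`, `highpass_order` | 10, 4 | Hz | standard sEMG conditioning |
| `lowpass_hz`, `lowpass_order` | 1.0, 2 | Hz | top of the useful 0.5–1 Hz smoothing range; see below |
| `gamma1`, `gamma2` | −0.5, −0.5 | — | stable, critically-damped-like activation dynamics |
| `delay_s` | 0 | s | electromechanical delay; see below |
| `A`, `R` | 1, 1/A | — | mild nonlinearity; see below |
| `dead_band` | 0.02 | — | middle of the empirical 1–3 % range |
| `kappa` | 0.9 | — | holding threshold as a fraction of the calibration hold plateau |
| `trend_window_s`, `trend_hysteresis` | 0.25 s, `dead_band` | | least-squares slope window and flat band |
| `hold_dwell_s` | 0.15 | s | debounce for holding entry |
| `p_max` | 3 | — | gain saturation for degenerate extension entries |

Three defaults deserve their reasoning spelled out, because the design was
genuinely open.

**Low-pass cutoff 1.0 Hz and zero delay.** The causal low-pass dominates
the chain's group delay (`√2/ω_c ≈ 0.22 s` at 1 Hz, 0.28 s at 0.8 Hz).
Because calibration pairs the *lagged* activation with the *current* angle
on the rising ramp, the fitted map absorbs the delay during flexion — and
re-incurs it with the opposite sign during extension, where the angle
moves the other way. Every 0.1 s of chain delay therefore costs about 6°
of extension over-prediction at 30°/s. The cutoff sits at the top of the
useful smoothing range, and the electromechanical-delay term defaults to
zero; for real recordings `delay_s` should be set to the subject's
EMG-to-force latency (30–100 ms is physiological), which in a real plant
is partly cancelled because EMG *leads* motion by the same latency.

**Nonlinearity shape `A = 1`.** The exponential excitation-to-activation
curve is convex for `A > 0`; large `A` compresses small activations (late
movement-onset detection) and bends the composite activation↔`cos²θ`
relation away from the quadratic form the calibration relies on (with
`A = 2` the fitted quadratic became non-monotone near its top). `A = 1`
keeps the curvature mild; the calibration quadratic absorbs what remains.
More linear still (`A → 0`) measurably degrades tracking, so the curvature
is not merely tolerated — it shapes the map's well-conditioned mid-range.

**Plateau-referenced holding threshold.** The flexion activation peak
includes the overshoot; the isometric plateau sits at roughly
`1/overshoot^elasticity ≈ 0.78–0.85` of it. A threshold at 0.9 of the
*peak* would therefore lie above the plateau and no hold could persist.
When the calibration trial contains a hold, the threshold is
`kappa ×` the median activation over the second half of that hold (the
overshoot has relaxed by then); a trial without a hold falls back to
`kappa ×` flexion peak.

## State-machine robustness

Three mechanisms keep the switching model stable against envelope noise,
all inside the four-state transition graph:

* **Holding-entry dwell** (150 ms): the dead-band staircase pauses during
  a perfectly good ramp; a single flat-classified sample must not freeze
  the hold angle 15–20° low.
* **Ratcheting hold angle**: while holding with a rising trend, the held
  angle updates upward through the map (never down) — the flexion had
  evidently not ended when the trend detector paused.
* **Schmitt trigger for re-flexion**: leaving extension for flexion
  requires the activation to rise at least `2 × dead_band` above the
  running minimum of the current extension episode, so jitter around a
  plateau cannot flip states and discard the continuity gain.

A falling trend in flexion at or below `holding_threshold × (1 −
dead_band)` enters extension directly (continuity makes the gain ≈ 1
there); without this path a noise-induced flexion episode during descent
would strand the machine without its gain correction.

## What the synthetic generator emulates — and what it does not

The generator inverts a known monotone quadratic map (default
`cos²θ = 1 − 1.4a − a²/3`, which places the 90°-hold demand at `a ≈ 0.62`,
a submaximal contraction with headroom for the overshoot) to obtain the
isometric activation demand for a commanded trajectory; multiplies it by
`overshoot_factor` (1.15) while the angle rises, relaxing exponentially
(τ = 150 ms) when the rise stops; adds multiplicative low-pass (2 Hz)
Gaussian envelope jitter (s.d. 0.05); and amplitude-modulates band-limited
(20–450 Hz) Gaussian noise — the standard surface-EMG interference model.
Trajectories follow the two experimental motion scripts: a 0→90°
trapezoid at 30°/s with a 3 s hold, and staircases of 10/20/30°
increments with 3 s holds.

It does **not** emulate: the electromechanical lead of real EMG over
motion (the synthetic envelope is synchronous with the angle, which makes
the chain-delay artifact described above *worse* than in real data),
motor-unit structure, electrode lift or slide, fatigue drift, or a faster
activation drop at extension onset than the map implies (real biceps EMG
falls quickly when the load is released; the generator's extension branch
follows the same quadratic map, which near 90° is almost flat, so the
descent of the envelope is initially very slow and switching detection
latencies are correspondingly pessimistic). Passing the closed-loop tests
therefore demonstrates the pipeline's internal consistency under a
noise model it assumes, not performance on human recordings.

## Numerical choices and degenerate inputs

* Filters are causal throughout (no zero-phase passes): the pipeline is a
  real-time control reference, and calibration uses the same causal chain.
* Filter states initialize to zero; traces are assumed to start at rest.
* The inverse map clamps the quadratic's value to [0, 1] before
  `arccos(√·)` — envelope noise routinely pushes the polynomial outside —
  and uses the positive root branch, valid because θ ∈ [0°, 90°].
* `sinh` overflow in the force–velocity factor is saturated so the
  analytic asymptotes (0 and 0.1433/0.1074) are returned instead of NaN.
* A non-monotone fitted quadratic is recorded as a warning in the model,
  not rejected; inversion remains total through clamping.
* A degenerate extension entry (`θ′_max ≤ 0`) saturates the gain at
  `p_max` with a warning.
* Zero-variance activation, empty MVC lists, all-zero MVC trials,
  non-uniform time grids and malformed CSV rows raise explicit errors
  (the CSV reader names the offending line).

## Problem sizes used in the checks

The packaged checks run the full protocol at its native scale — 1000 Hz,
10 trials per condition, 9 s continuous trials and 24–36 s stepping
trials, 20 calibration replicates of 500 samples — and property suites at
reduced scale (hundreds of random signals of a few hundred samples), a
deliberate balance between coverage and turnaround.

## Known limitations

Measured on the synthetic study conditions (calibrate on one trial,
predict nine held-out trials), mean RMS tracking error is ≈ 10–11° for the
continuous trapezoid and ≈ 6–7° for 20° and 30° stepping staircases. The
error concentrates where the method is structurally insensitive:

* **Movement onset**: the inactivation level plus the dead-band floor keep
  the output at 0° until the true angle reaches ~20°.
* **Near full flexion**: `d(cos²θ)/dθ → 0` at 90°, so a 1–3 % activation
  dead band freezes the output several degrees below the top; sub-degree
  closed-loop recovery is achievable only in the map's well-conditioned
  mid-range.
* **Hold sag and descent bias**: one quadratic serves both the overshoot
  (concentric) and plateau (isometric) activation branches; the ~15 %
  branch mismatch must surface either as a sagging hold or as an inflated
  descent, and the chain delay adds a descent over-prediction of
  ~2 × delay × angular velocity.

These are properties of the single-channel, single-map method itself
under this noise model, not of the implementation; the module tests pin
the behaviour quantitatively.
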