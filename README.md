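# emgangle

Continuous elbow-joint angle estimation from a single channel of surface
electromyography (EMG) recorded over the biceps brachii, for voluntary
flexion and extension in the sagittal plane. The intended user is anyone
building or studying myoelectric control of upper-limb devices — e.g. a
rehabilitation exoskeleton driven bilaterally by the intact arm's EMG —
who needs a smooth, continuous joint-angle reference rather than discrete
gesture classes, from one electrode and one short calibration trial.

## Method

Raw EMG is conditioned (4th-order 10 Hz Butterworth high-pass,
rectification), converted to neural excitation by the second-order
recursive activation-dynamics filter

    u(t) = α e(t − d) − β₁ u(t−1) − β₂ u(t−2),
    β₁ = γ₁ + γ₂,  β₂ = γ₁ γ₂,  α = 1 + β₁ + β₂,  |γᵢ| < 1,

low-pass smoothed (2nd-order Butterworth, 0.5–1 Hz), normalized to the
maximum voluntary contraction (MVC), and mapped to muscle activation by
`a(u) = (e^{u/R} − 1)/(e^A − 1)`. A Hill-type musculotendon model of the
biceps (contractile element `F = F_max · a · f_l · f_v` with the elbow
geometry `ΔL_CE = α L_CE0 cos θ`, `V_CE/V_CE0 = −0.1 α θ̇ sin θ`) reduces,
for slow sagittal movements, to a quadratic relation between `cos²θ` and
scaled activation, fitted per subject from one calibration trial by least
squares. A four-state switching model — relaxation, flexion, holding,
extension — converts the activation trace into a continuous angle: flexion
inverts the fitted map, holding freezes the last flexion angle, and
extension rescales the map by the proportional gain `p = θ_max / θ′_max`
so the output is continuous across the transition. A synthetic
surface-EMG generator (amplitude-modulated band-limited Gaussian noise
driven by the forward model, including the flexion→holding activation
overshoot) makes the whole pipeline testable without recordings.

## Worked example

Simulate a session, calibrate on one trial, predict a held-out trial:

```r
library(emgangle)

config  <- emg_config()
subject <- synthetic_subject()
session <- generate_dataset(trajectory_spec("continuous"), subject,
                            n_trials = 2, seed = 42)

mvc   <- compute_mvc(session$mvc, config)
model <- calibrate(session$trials[[1]], mvc, config)
model
#> Calibration model: cos^2(theta) ~ quadratic in a/R
#>   coefficients (a0, a1, a2): 0.970599, -3.07875, 2.37458
#>   R = 1, fit_r = 0.9990, n = 3017
#>   holding_threshold = 0.4034, inactivation_level = 0.0266

pred   <- predict_angles(session$trials[[2]], model, mvc, config)
report <- evaluate_prediction(pred, session$trials[[2]]$angle_deg)
glance(report)
#> # A tibble: 1 × 4
#>   rms_error correlation lag_s     n
#>       <dbl>       <dbl> <dbl> <int>
#> 1      11.4       0.937     0  9000

tidy(report)   # per-state RMS error, degrees
#> # A tibble: 4 × 2
#>   state      rms_error
#>   <chr>          <dbl>
#> 1 extension      13.4
#> 2 flexion         5.83
#> 3 holding        13.1
#> 4 relaxation     10.4
```

The fitted quadratic explains the flexion-phase relation almost perfectly
(`fit_r = 0.999`, matching the >0.97 expected of a good calibration).
Tracking error on the held-out trial is ≈11° RMS overall with correlation
0.94; the per-state breakdown shows the error concentrating at movement
onset (output pinned at 0° until activation clears the inactivation
level), near full flexion (where `cos²θ` is flat and the dead band
freezes the staircase), and on the extension descent (processing-chain
lag) — see the methods vignette for why. `autoplot(pred, truth = ...)`
draws the predicted trajectory coloured by state over the ground truth.

A command-line interface wrapping the same functions is installed at
`system.file("exec", "emgangle", package = "emgangle")`, with subcommands
`simulate`, `calibrate`, `predict` and `evaluate` operating on CSV signal
files (`time_s, emg[, angle_deg]`) and flat JSON model files.

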