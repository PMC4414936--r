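# Shared fixtures: everything is generated in code at test time.

default_fs <- 1000

# A small, fast closed-loop dataset: continuous trapezoid, few trials.
make_closed_loop <- function(n_trials = 3, seed = 5, jitter = 0.05,
                             spec = trajectory_spec("continuous"),
                             config = emg_config()) {
  sub <- synthetic_subject(envelope_jitter = jitter)
  ds <- generate_dataset(spec, sub, n_trials = n_trials, seed = seed)
  mvc <- compute_mvc(ds$mvc, config)
  model <- calibrate(ds$trials[[1]], mvc, config)
  list(ds = ds, mvc = mvc, model = model, config = config, subject = sub)
}

# Noise-free "direct activation" loop: the generator's envelope is fed to
# the state machine as the activation trace, bypassing EMG synthesis, and
# the calibration map is fitted on the same noise-free pairs.
make_direct_loop <- function(spec = trajectory_spec("continuous"),
                             config = emg_config(),
                             subject = synthetic_subject(envelope_jitter = 0)) {
  traj <- make_trajectory(spec, default_fs)
  env <- trajectory_to_envelope(traj, subject)
  fm <- detect_flexion_phase(env$angle_deg, default_fs)
  hm <- tryCatch(detect_holding_phase(env$angle_deg, default_fs),
                 error = function(e) NULL)
  if (!is.null(hm) && !any(hm)) hm <- NULL
  model <- fit_quadratic_map(env$envelope, env$angle_deg, fm,
                             holding_mask = hm, config = config)
  act <- emg_trace(env$envelope, default_fs, stage = "activation")
  list(env = env, model = model, act = act, flexion = fm, config = config)
}

# A calibration model with known coefficients, for unit tests that need a
# fitted model without running the generator.
make_known_model <- function(coeffs = c(1, -0.8, -0.2), R = 1,
                             holding_threshold = 0.6,
                             inactivation_level = 0.05,
                             dead_band = 0.02) {
  structure(
    list(poly_coeffs = coeffs, R = R,
         holding_threshold = holding_threshold,
         inactivation_level = inactivation_level,
         fit_r = 1, peak_activation = 1, plateau_activation = NA_real_,
         dead_band = dead_band, monotone = TRUE, n_fit = 0L),
    class = "calibration_model"
  )
}
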