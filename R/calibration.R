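#' Fit the quadratic activation-to-angle calibration map
#'
#' Fits, by least squares, a quadratic polynomial from scaled activation
#' `a / R` to `cos^2(theta)` using only flexion-phase samples of one
#' calibration trial, and derives the state-machine thresholds. The holding
#' threshold is referenced to the *isometric plateau*: the activation level
#' during flexion transiently exceeds the level needed to hold the same
#' angle (the acceleration torque disappears when the arm stops, so the
#' activation overshoots and then relaxes), and a threshold referenced to
#' the flexion peak would sit above the plateau and break every hold.
#' When `holding_mask` marks an isometric hold in the calibration trial,
#' `holding_threshold = kappa * median(activation over the second half of
#' the hold)`; without a hold it falls back to `kappa * flexion peak`.
#' The inactivation level is `max(dead_band, 5 % of the flexion peak)`.
#'
#' The elbow-angle convention is 0 degrees at full
#' extension (arm relaxed vertically) and 90 degrees with the forearm
#' horizontal, so `cos^2(theta)` decreases from 1 to 0 as activation rises
#' during flexion and the fitted map is monotone decreasing over the
#' calibrated range (a non-monotone fit is recorded as a warning in the
#' model rather than rejected).
#'
#' @param activation Activation samples in \[0, 1\] (an [emg_trace()] at
#'   stage `"activation"` or a bare numeric vector).
#' @param angles Elbow angles in degrees, in \[0, 90\], same length.
#' @param flexion_mask Logical vector marking flexion-phase samples
#'   (e.g. from [detect_flexion_phase()]); needs >= 10 `TRUE` entries.
#' @param holding_mask Optional logical vector marking isometric-hold
#'   samples (e.g. from [detect_holding_phase()]); used to reference the
#'   holding threshold to the plateau activation.
#' @param config An [emg_config()]; supplies `R`, `kappa` and `dead_band`.
#' @return A list of class `calibration_model` with elements `poly_coeffs`
#'   (a0, a1, a2), `R`, `holding_threshold`, `inactivation_level`, `fit_r`
#'   (Pearson correlation between fitted and observed `cos^2(theta)`),
#'   `peak_activation`, `dead_band`, `monotone` and `n_fit`.
#' @export
fit_quadratic_map <- function(activation, angles, flexion_mask,
                              holding_mask = NULL,
                              config = emg_config()) {
  a <- if (inherits(activation, "emg_trace")) trace_samples(activation)
       else activation
  stopifnot(length(a) == length(angles), length(a) == length(flexion_mask))
  if (any(angles < 0 | angles > 90)) {
    abort("`angles` must lie in [0, 90] degrees.")
  }
  if (any(a < 0 | a > 1)) abort("`activation` must lie in [0, 1].")
  if (sum(flexion_mask) < 10L) {
    abort("Need at least 10 flexion-phase samples to calibrate.")
  }
  af <- a[flexion_mask]
  y <- cos(deg2rad(angles[flexion_mask]))^2
  if (stats::var(af) == 0) {
    abort("Degenerate fit: activation is constant over the flexion phase.")
  }
  x <- af / config$R
  fit <- lm(y ~ x + I(x^2))
  cf <- unname(coef(fit))
  cf[is.na(cf)] <- 0
  fitted_y <- fitted(fit)
  fit_r <- if (stats::var(fitted_y) > 0) cor(fitted_y, y) else NA_real_
  # monotone decreasing over the observed scaled-activation range?
  dpoly <- function(z) cf[2L] + 2 * cf[3L] * z
  rng <- range(x)
  monotone <- all(dpoly(seq(rng[1L], rng[2L], length.out = 101L)) <= 0)
  if (!monotone) {
    warn("Fitted quadratic map is not monotone over the calibrated range.")
  }
  peak <- max(af)
  plateau <- NA_real_
  if (!is.null(holding_mask) && sum(holding_mask) >= 10L) {
    # second half of the hold: the flexion overshoot has relaxed by then
    idx <- which(holding_mask)
    idx <- idx[idx > idx[ceiling(length(idx) / 2)]]
    if (length(idx) >= 5L) plateau <- median(a[idx])
  }
  threshold_ref <- if (is.finite(plateau)) plateau else peak
  model <- structure(
    list(
      poly_coeffs = cf,
      R = config$R,
      holding_threshold = config$kappa * threshold_ref,
      inactivation_level = max(config$dead_band, 0.05 * peak),
      fit_r = fit_r,
      peak_activation = peak,
      plateau_activation = plateau,
      dead_band = config$dead_band,
      monotone = monotone,
      n_fit = length(af)
    ),
    class = "calibration_model"
  )
  stopifnot(model$inactivation_level < model$holding_threshold)
  model
}

#' Invert the calibration map: activation to elbow angle
#'
#' Evaluates the fitted quadratic at `a / R`, clamps the predicted
#' `cos^2(theta)` to \[0, 1\], and returns
#' `theta = acos(sqrt(.))` in degrees. Because theta is confined to
#' \[0, 90\] degrees the positive square-root/arccos branch is the valid
#' inverse; clamping makes the operation total for any real activation
#' input.
#'
#' @param a Activation value(s).
#' @param model A fitted `calibration_model`.
#' @return Elbow angle(s) in degrees, in \[0, 90\].
#' @export
invert_map <- function(a, model) {
  stopifnot(inherits(model, "calibration_model"))
  y <- clamp(quadratic_model_value(a, model$poly_coeffs, model$R), 0, 1)
  rad2deg(acos(sqrt(y)))
}

#' Detect the flexion phase of a calibration trial
#'
#' Marks samples whose smoothed angular velocity exceeds
#' `+dtheta_threshold`; contiguous runs shorter than `min_run_s` are
#' discarded as noise. Velocity is estimated by central differences of a
#' moving-average-smoothed angle series.
#'
#' @param angles Angle series in degrees, uniformly sampled.
#' @param sampling_rate Sampling rate, Hz.
#' @param dtheta_threshold Velocity threshold, degrees per second.
#' @param min_run_s Minimum duration of a flexion run, seconds.
#' @return A logical vector the length of `angles`.
#' @export
detect_flexion_phase <- function(angles, sampling_rate,
                                 dtheta_threshold = 5, min_run_s = 0.2) {
  n <- length(angles)
  w <- max(3L, round(0.05 * sampling_rate))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- as.numeric(stats::filter(angles, rep(1 / w, w), sides = 2))
  # pad the ends, where the moving average is undefined
  sm[is.na(sm)] <- angles[is.na(sm)]
  vel <- c(0, diff(sm)) * sampling_rate
  mask <- vel > dtheta_threshold
  # drop runs shorter than min_run_s
  r <- rle(mask)
  min_len <- round(min_run_s * sampling_rate)
  r$values[r$values & r$lengths < min_len] <- FALSE
  mask <- inverse.rle(r)
  if (!any(mask)) {
    abort("No flexion segment found: no sustained positive angular velocity.")
  }
  mask
}

#' Detect the isometric holding phase of a calibration trial
#'
#' Marks samples where the smoothed angular velocity is within
#' `dtheta_threshold` of zero while the angle is near its maximum (above
#' `level_frac` of the trial peak); runs shorter than `min_run_s` are
#' discarded. Returns all-`FALSE` (no error) when the trial has no hold,
#' e.g. a triangle motion.
#'
#' @inheritParams detect_flexion_phase
#' @param level_frac Fraction of the peak angle above which a sample can
#'   count as holding.
#' @return A logical vector the length of `angles`.
#' @export
detect_holding_phase <- function(angles, sampling_rate,
                                 dtheta_threshold = 5, min_run_s = 0.5,
                                 level_frac = 0.9) {
  n <- length(angles)
  w <- max(3L, round(0.05 * sampling_rate))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- as.numeric(stats::filter(angles, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- angles[is.na(sm)]
  vel <- c(0, diff(sm)) * sampling_rate
  mask <- abs(vel) < dtheta_threshold & angles > level_frac * max(angles)
  r <- rle(mask)
  r$values[r$values & r$lengths < round(min_run_s * sampling_rate)] <- FALSE
  inverse.rle(r)
}

#' Calibrate from one trial
#'
#' Convenience wrapper: processes the raw EMG of a calibration trial (a
#' tibble with `time_s`, `emg`, `angle_deg`), detects the flexion phase
#' from the recorded angles, and fits the calibration map.
#'
#' @param trial A tibble with columns `time_s`, `emg`, `angle_deg` (e.g.
#'   from [read_emg_csv()] or [generate_dataset()]).
#' @param mvc_value MVC normalization constant from [compute_mvc()].
#' @param config An [emg_config()].
#' @return A `calibration_model`.
#' @export
calibrate <- function(trial, mvc_value, config = emg_config()) {
  if (!all(c("time_s", "emg", "angle_deg") %in% names(trial))) {
    abort("Calibration trial needs columns `time_s`, `emg`, `angle_deg`.")
  }
  act <- process_emg(trial, mvc_value, config)
  fs <- sampling_rate(act)
  fmask <- detect_flexion_phase(trial$angle_deg, fs)
  hmask <- detect_holding_phase(trial$angle_deg, fs)
  fit_quadratic_map(act, trial$angle_deg, fmask, holding_mask = hmask,
                    config = config)
}

#' Read or write a calibration model file
#'
#' Models are serialized to a flat key-value JSON file (calibration is per
#' subject and per session; the offline calibration result is carried to
#' online use through this file).
#'
#' @param path File path.
#' @return `read_calibration_model()` returns a `calibration_model`.
#' @export
read_calibration_model <- function(path) {
  vals <- read_flat_file(path)
  need <- c("poly_coeffs", "R", "holding_threshold", "inactivation_level")
  if (!all(need %in% names(vals))) {
    abort(sprintf("%s: not a calibration model file.", path))
  }
  structure(vals, class = "calibration_model")
}

#' @rdname read_calibration_model
#' @param model A `calibration_model`.
#' @export
write_calibration_model <- function(model, path) {
  write_flat_file(unclass(model), path)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Calibration model: cos^2(theta) ~ quadratic in a/R\n")
  cat(sprintf("  coefficients (a0, a1, a2): %s\n",
              paste(signif(x$poly_coeffs, 6), collapse = ", ")))
  cat(sprintf("  R = %g, fit_r = %.4f, n = %d\n", x$R, x$fit_r, x$n_fit))
  cat(sprintf("  holding_threshold = %.4f, inactivation_level = %.4f\n",
              x$holding_threshold, x$inactivation_level))
  if (!isTRUE(x$monotone)) cat("  warning: fitted map not monotone\n")
  invisible(x)
}

#' Tidy a calibration model
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return A tibble with one row per polynomial term.
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "a/R", "(a/R)^2"),
    estimate = x$poly_coeffs
  )
}

#' @rdname tidy.calibration_model
#' @return `glance()` returns a one-row tibble with the fit summary.
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(
    fit_r = x$fit_r,
    n_fit = x$n_fit,
    R = x$R,
    peak_activation = x$peak_activation,
    holding_threshold = x$holding_threshold,
    inactivation_level = x$inactivation_level,
    monotone = isTRUE(x$monotone)
  )
}
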