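#' Synthetic subject parameters
#'
#' Forward-model parameters for the surface-EMG surrogate generator. The
#' generator emulates the statistical structure the estimation method
#' assumes: a monotone decreasing quadratic map from activation to
#' `cos^2(theta)` during flexion; a multiplicative activation excess
#' ("overshoot") while the arm accelerates in flexion, relaxing
#' exponentially (150 ms time constant) once the movement stops; a plateau
#' during holding; and a monotone decay during extension. The raw signal is
#' amplitude-modulated band-limited Gaussian noise — the standard surface-EMG
#' interference model.
#'
#' The default map `cos^2(theta) = 1 - 1.4 a - a^2/3` reaches zero (full
#' flexion, 90 degrees) at an activation of about 0.62: holding the forearm
#' horizontal against gravity is a submaximal contraction, well below the
#' MVC level, which leaves headroom for the flexion overshoot.
#'
#' @param true_poly Coefficients `(a0, a1, a2)` of the generating map from
#'   activation to `cos^2(theta)`; must be monotone decreasing on \[0, 1\]
#'   with `a0 = 1` (zero activation at full extension).
#' @param overshoot_factor Multiplicative activation excess during flexion
#'   relative to the isometric demand (>= 1).
#' @param mvc_scale Raw-EMG amplitude scale at full activation, voltage
#'   units.
#' @param noise_band Carrier noise band `(low, high)` in Hz.
#' @param envelope_jitter Relative s.d. of the multiplicative envelope
#'   noise (low-passed at 2 Hz).
#' @return A list of class `synthetic_subject`.
#' @export
synthetic_subject <- function(true_poly = c(1, -1.4, -1 / 3),
                              overshoot_factor = 1.15,
                              mvc_scale = 1,
                              noise_band = c(20, 450),
                              envelope_jitter = 0.05) {
  stopifnot(length(true_poly) == 3L)
  # monotone decreasing on [0, 1]: derivative a1 + 2 a2 x <= 0 at both ends
  if (true_poly[2L] > 0 || true_poly[2L] + 2 * true_poly[3L] > 0) {
    abort("`true_poly` must be monotone decreasing on [0, 1].")
  }
  if (overshoot_factor < 1) abort("`overshoot_factor` must be >= 1.")
  if (mvc_scale <= 0) abort("`mvc_scale` must be > 0.")
  if (envelope_jitter < 0) abort("`envelope_jitter` must be >= 0.")
  structure(
    list(true_poly = true_poly, overshoot_factor = overshoot_factor,
         mvc_scale = mvc_scale, noise_band = noise_band,
         envelope_jitter = envelope_jitter),
    class = "synthetic_subject"
  )
}

#' Trajectory specification
#'
#' Describes the commanded elbow trajectory of a synthetic trial, matching
#' the two experimental motion scripts: a continuous
#' flexion-hold-extension trapezoid, or a consecutive stepping staircase.
#'
#' @param kind `"continuous"` or `"stepping"`.
#' @param ramp_rate Angular velocity of the ramps, degrees per second.
#' @param hold_s Hold duration at each plateau, seconds.
#' @param step_increment Step size for `kind = "stepping"`, degrees.
#' @param peak_deg Peak angle, degrees in (0, 90\].
#' @return A list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(kind = c("continuous", "stepping"),
                            ramp_rate = 30, hold_s = 3,
                            step_increment = 30, peak_deg = 90) {
  kind <- match.arg(kind)
  if (peak_deg <= 0 || peak_deg > 90) abort("`peak_deg` must be in (0, 90].")
  if (ramp_rate <= 0) abort("`ramp_rate` must be > 0.")
  if (hold_s < 0) abort("`hold_s` must be >= 0.")
  if (kind == "stepping" && step_increment <= 0) {
    abort("`step_increment` must be > 0.")
  }
  structure(
    list(kind = kind, ramp_rate = ramp_rate, hold_s = hold_s,
         step_increment = step_increment, peak_deg = peak_deg),
    class = "trajectory_spec"
  )
}

#' Generate a ground-truth angle trajectory
#'
#' Continuous trials are a trapezoid: ramp from 0 to `peak_deg` at
#' `ramp_rate`, hold for `hold_s`, ramp back to 0 (with `hold_s = 0` this
#' degenerates to a triangle). Stepping trials are a staircase of
#' `step_increment` rises, each followed by a hold, up to `peak_deg`, then
#' the symmetric descent with a hold after each fall; an increment that
#' does not divide the peak truncates the last step with a warning.
#'
#' @param spec A [trajectory_spec()].
#' @param sampling_rate Sampling rate, Hz.
#' @return A tibble with columns `time_s` and `angle_deg`, piecewise
#'   linear, starting and ending at 0.
#' @export
make_trajectory <- function(spec, sampling_rate = 1000) {
  stopifnot(inherits(spec, "trajectory_spec"))
  # build (duration, target-angle) knots, then sample
  if (spec$kind == "continuous") {
    ramp_t <- spec$peak_deg / spec$ramp_rate
    knots <- rbind(
      c(ramp_t, spec$peak_deg),
      c(spec$hold_s, spec$peak_deg),
      c(ramp_t, 0)
    )
  } else {
    steps <- seq(spec$step_increment, spec$peak_deg, by = spec$step_increment)
    if (tail(steps, 1L) < spec$peak_deg) {
      warn(sprintf(
        "Step increment %g does not divide peak %g; last step truncated to %g.",
        spec$step_increment, spec$peak_deg,
        spec$peak_deg - tail(steps, 1L)
      ))
      steps <- c(steps, spec$peak_deg)
    }
    up <- steps
    down <- rev(c(0, head(steps, -1L)))
    lvls <- c(up, down)
    prev <- c(0, head(lvls, -1L))
    knots <- do.call(rbind, lapply(seq_along(lvls), function(i) {
      rbind(
        c(abs(lvls[i] - prev[i]) / spec$ramp_rate, lvls[i]),
        c(spec$hold_s, lvls[i])
      )
    }))
  }
  knots <- knots[knots[, 1L] > 0, , drop = FALSE]  # drop zero-length holds
  t_knot <- cumsum(c(0, knots[, 1L]))
  a_knot <- c(0, knots[, 2L])
  total <- tail(t_knot, 1L)
  n <- round(total * sampling_rate)
  time_s <- seq(0, by = 1 / sampling_rate, length.out = n)
  angle <- approx(t_knot, a_knot, xout = time_s, rule = 2)$y
  tibble(time_s = time_s, angle_deg = angle)
}

#' Forward model: trajectory to activation envelope
#'
#' Inverts the subject's generating map to obtain the isometric activation
#' demand `a_base(t)` for each angle, then applies the flexion overshoot:
#' while the angle is rising, the envelope is
#' `overshoot_factor * a_base`; when the rise stops, the excess relaxes
#' exponentially back to `a_base` with a 150 ms time constant, reproducing
#' the rapid-drop-then-plateau of the activation at the flexion-to-holding
#' transition. The envelope is clamped to \[0, 1\].
#'
#' @param trajectory A tibble from [make_trajectory()] (columns `time_s`,
#'   `angle_deg` in \[0, 90\]).
#' @param subject A [synthetic_subject()].
#' @param tau_s Overshoot relaxation time constant, seconds.
#' @return A tibble with columns `time_s`, `angle_deg`, `envelope`.
#' @export
trajectory_to_envelope <- function(trajectory, subject, tau_s = 0.15) {
  stopifnot(inherits(subject, "synthetic_subject"))
  th <- trajectory$angle_deg
  if (any(th < 0 | th > 90)) abort("Angles must lie in [0, 90] degrees.")
  a_base <- invert_true_poly(cos(deg2rad(th))^2, subject$true_poly)
  dt <- median(diff(trajectory$time_s))
  rising <- c(FALSE, diff(th) > 0)
  decay <- exp(-dt / tau_s)
  excess <- numeric(length(th))
  ex <- 0
  gain <- subject$overshoot_factor - 1
  for (i in seq_along(th)) {
    ex <- if (rising[i]) gain * a_base[i] else ex * decay
    excess[i] <- ex
  }
  tibble(
    time_s = trajectory$time_s,
    angle_deg = th,
    envelope = clamp(a_base + excess, 0, 1)
  )
}

# Invert y = a0 + a1 x + a2 x^2 for x in [0, 1]; the map is monotone
# decreasing, so the bracket [0, 1] contains exactly one root for y in
# [poly(1), poly(0)]; out-of-range y are clamped to the endpoints.
invert_true_poly <- function(y, poly) {
  a0 <- poly[1L]; a1 <- poly[2L]; a2 <- poly[3L]
  lo <- a0 + a1 + a2  # poly(1)
  y <- clamp(y, pmin(lo, a0), pmax(lo, a0))
  if (abs(a2) < 1e-12) {
    x <- (y - a0) / a1
  } else {
    disc <- a1^2 - 4 * a2 * (a0 - y)
    disc <- pmax(disc, 0)
    r1 <- (-a1 + sqrt(disc)) / (2 * a2)
    r2 <- (-a1 - sqrt(disc)) / (2 * a2)
    x <- ifelse(r1 >= -1e-9 & r1 <= 1 + 1e-9, r1, r2)
  }
  clamp(x, 0, 1)
}

#' Synthesize raw surface EMG from an activation envelope
#'
#' `raw(t) = mvc_scale * envelope(t) * (1 + jitter(t)) * n(t)` where `n(t)`
#' is zero-mean unit-variance Gaussian noise band-passed to the subject's
#' noise band (default 20-450 Hz) and `jitter` is zero-mean Gaussian with
#' s.d. `envelope_jitter`, low-passed at 2 Hz (both re-standardized after
#' filtering). Reproducible given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param envelope Numeric envelope in \[0, 1\], or a tibble with an
#'   `envelope` column from [trajectory_to_envelope()].
#' @param subject A [synthetic_subject()].
#' @param sampling_rate Sampling rate, Hz.
#' @param seed Integer RNG seed.
#' @return A raw [emg_trace()].
#' @export
envelope_to_raw_emg <- function(envelope, subject, sampling_rate = 1000,
                                seed = 1L) {
  if (is.data.frame(envelope)) envelope <- envelope$envelope
  if (any(envelope < 0 | envelope > 1)) {
    abort("`envelope` must lie in [0, 1].")
  }
  if (subject$noise_band[2L] >= sampling_rate / 2) {
    abort("Noise band must lie below the Nyquist frequency.")
  }
  n <- length(envelope)
  withr::with_seed(seed, {
    carrier <- rnorm(n)
    bf <- signal::butter(4, 2 * subject$noise_band / sampling_rate,
                         type = "pass")
    carrier <- as.numeric(signal::filter(bf, carrier))
    carrier <- carrier / max(sd(carrier), .Machine$double.eps)
    if (subject$envelope_jitter > 0) {
      jit <- rnorm(n)
      lf <- signal::butter(2, 2 * 2 / sampling_rate, type = "low")
      jit <- as.numeric(signal::filter(lf, jit))
      jit <- jit / max(sd(jit), .Machine$double.eps) * subject$envelope_jitter
    } else {
      jit <- numeric(n)
    }
    raw <- subject$mvc_scale * pmax(envelope * (1 + jit), 0) * carrier
    emg_trace(raw, sampling_rate, stage = "raw")
  })
}

#' Generate a synthetic dataset
#'
#' Produces `n_trials` independent (raw EMG, ground-truth angle) pairs for
#' one trajectory and subject, with per-trial seeds derived from `seed`
#' (`seed, seed + 1, ...`), plus one MVC trial (envelope held at 1 for
#' 3 s, seed `seed + n_trials`). The ground-truth angles are identical
#' across trials; only the noise realization differs.
#'
#' @param spec A [trajectory_spec()].
#' @param subject A [synthetic_subject()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Base integer seed.
#' @param sampling_rate Sampling rate, Hz.
#' @return A list with elements `trials` (list of tibbles with `time_s`,
#'   `emg`, `angle_deg`), `mvc` (a raw [emg_trace()]), `trajectory`,
#'   `envelope`, and the generating `spec`, `subject`, `seed`.
#' @export
generate_dataset <- function(spec, subject, n_trials = 1, seed = 1L,
                             sampling_rate = 1000) {
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  traj <- make_trajectory(spec, sampling_rate)
  env <- trajectory_to_envelope(traj, subject)
  trials <- purrr::map(seq_len(n_trials), function(i) {
    tr <- envelope_to_raw_emg(env, subject, sampling_rate,
                              seed = seed + i - 1L)
    tibble(time_s = env$time_s, emg = trace_samples(tr),
           angle_deg = env$angle_deg)
  })
  mvc_env <- rep(1, round(3 * sampling_rate))
  mvc <- envelope_to_raw_emg(mvc_env, subject, sampling_rate,
                             seed = seed + n_trials)
  list(trials = trials, mvc = mvc, trajectory = traj, envelope = env,
       spec = spec, subject = subject, seed = seed)
}
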