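#' High-pass filter raw EMG
#'
#' Applies a causal Butterworth high-pass filter (default 4th order, 10 Hz
#' cutoff) to remove DC offset and low-frequency motion artifact from raw
#' surface EMG before rectification. Filtering is sample-by-sample from zero
#' initial conditions: no zero-phase (forward-backward) pass is used, so the
#' same chain is valid for real-time use.
#'
#' @param trace An [emg_trace()] at stage `"raw"`.
#' @param cutoff_hz Cutoff frequency in Hz, strictly between 0 and Nyquist.
#' @param order Filter order (>= 1).
#' @return The filtered trace at stage `"highpassed"`, same length.
#' @export
highpass_filter <- function(trace, cutoff_hz = 10, order = 4) {
  check_stage(trace, "raw", "highpass_filter")
  fs <- sampling_rate(trace)
  check_cutoff(cutoff_hz, fs)
  if (order < 1) abort("`order` must be >= 1.")
  bf <- signal::butter(order, 2 * cutoff_hz / fs, type = "high")
  y <- as.numeric(signal::filter(bf, trace_samples(trace)))
  retrace(trace, y, "highpassed")
}

#' Full-wave rectify an EMG trace
#'
#' @param trace An [emg_trace()] at stage `"highpassed"`.
#' @return The absolute-value trace at stage `"rectified"`.
#' @export
rectify <- function(trace) {
  check_stage(trace, c("highpassed", "rectified"), "rectify")
  retrace(trace, abs(trace_samples(trace)), "rectified")
}

#' Activation-dynamics filter coefficients
#'
#' Builds the coefficients of the second-order recursive filter
#' `u(t) = alpha * e(t - d) - beta1 * u(t-1) - beta2 * u(t-2)` that turns
#' rectified EMG into neural excitation. The recursion is parameterized by
#' two poles `gamma1`, `gamma2` (both of magnitude < 1 for stability):
#' `beta1 = gamma1 + gamma2`, `beta2 = gamma1 * gamma2`, and
#' `alpha = 1 + beta1 + beta2` so that the DC gain
#' `alpha / (1 + beta1 + beta2)` is exactly 1 and a bounded excitation never
#' exceeds its driving input in steady state.
#'
#' @param gamma1,gamma2 Recursive poles, `|gamma| < 1`.
#' @param delay_samples Electromechanical delay `d` in samples (a
#'   non-negative integer): the latency between EMG onset and force
#'   production.
#' @return A list of class `filter_coefficients` with elements `alpha`,
#'   `beta1`, `beta2`, `gamma1`, `gamma2`, `delay_samples`.
#' @export
#' @examples
#' make_filter_coefficients(-0.5, -0.5, 50)
make_filter_coefficients <- function(gamma1, gamma2, delay_samples = 0L) {
  if (abs(gamma1) >= 1 || abs(gamma2) >= 1) {
    abort("Unstable activation dynamics: need |gamma1| < 1 and |gamma2| < 1.")
  }
  if (delay_samples < 0 || delay_samples != round(delay_samples)) {
    abort("`delay_samples` must be a non-negative integer.")
  }
  beta1 <- gamma1 + gamma2
  beta2 <- gamma1 * gamma2
  structure(
    list(
      alpha = 1 + beta1 + beta2, beta1 = beta1, beta2 = beta2,
      gamma1 = gamma1, gamma2 = gamma2,
      delay_samples = as.integer(round(delay_samples))
    ),
    class = "filter_coefficients"
  )
}

#' Activation dynamics (rectified EMG to neural excitation)
#'
#' Runs the recursive difference equation
#' `u(t) = alpha * e(t - d) - beta1 * u(t-1) - beta2 * u(t-2)` over a
#' rectified trace, with `u(t) = 0` and `e(t) = 0` for `t < 0` (traces are
#' assumed to start at rest). By construction of the coefficients the filter
#' has unity DC gain, so a constant input is reproduced in steady state.
#'
#' @param e An [emg_trace()] at stage `"rectified"`.
#' @param coeffs A [make_filter_coefficients()] object.
#' @return The excitation trace, stage `"excitation"`.
#' @export
activation_dynamics <- function(e, coeffs) {
  check_stage(e, "rectified", "activation_dynamics")
  stopifnot(inherits(coeffs, "filter_coefficients"))
  x <- trace_samples(e)
  d <- coeffs$delay_samples
  b <- c(rep(0, d), coeffs$alpha)           # numerator: alpha * z^-d
  a <- c(1, coeffs$beta1, coeffs$beta2)     # denominator
  u <- as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
  retrace(e, u, "excitation")
}

#' Low-pass smooth the neural excitation
#'
#' Causal Butterworth low-pass with unity DC gain. The muscle acts as a
#' mechanical low-pass, so force changes far more slowly than the EMG
#' interference pattern; a cutoff around 0.5-1 Hz (default 0.8 Hz, order 2)
#' sacrifices some signal energy for a smooth activation estimate, which is
#' appropriate when the goal is a joint-angle reference rather than clinical
#' EMG analysis.
#'
#' @param u An [emg_trace()] at stage `"excitation"` (or `"rectified"`, as
#'   used when estimating the MVC envelope).
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param order Filter order.
#' @return A smoothed trace at the same stage.
#' @export
lowpass_smooth <- function(u, cutoff_hz = 0.8, order = 2) {
  check_stage(u, c("excitation", "rectified"), "lowpass_smooth")
  fs <- sampling_rate(u)
  check_cutoff(cutoff_hz, fs)
  bf <- signal::butter(order, 2 * cutoff_hz / fs, type = "low")
  y <- as.numeric(signal::filter(bf, trace_samples(u)))
  if (emg_stage(u) == "rectified") y <- pmax(y, 0)
  retrace(u, y, emg_stage(u))
}

#' Exponential activation nonlinearity
#'
#' Maps MVC-normalized neural excitation `u` to muscle activation
#' `a(u) = (exp(u / R) - 1) / (exp(A) - 1)`, clamped to \[0, 1\]. With the
#' default `R = 1/A` the normalized excitation range \[0, 1\] maps exactly
#' onto activation \[0, 1\]; `A` controls the curvature of the
#' excitation-to-activation relationship.
#'
#' @param u An [emg_trace()] at stage `"excitation"`, MVC-normalized so that
#'   samples lie in (approximately) \[0, R*A\].
#' @param A Shape parameter (> 0).
#' @param R Excitation scaling (> 0).
#' @return An activation trace at stage `"activation"`, values in \[0, 1\].
#' @export
#' @examples
#' tr <- emg_trace(c(0, 0.5, 1), 1000, stage = "excitation")
#' activation_nonlinearity(tr, A = 2, R = 0.5)
activation_nonlinearity <- function(u, A = 2, R = 1 / A) {
  check_stage(u, "excitation", "activation_nonlinearity")
  if (A <= 0) abort("Degenerate nonlinearity: `A` must be > 0.")
  if (R <= 0) abort("`R` must be > 0.")
  x <- trace_samples(u)
  a <- (exp(x / R) - 1) / (exp(A) - 1)
  retrace(u, clamp(a, 0, 1), "activation")
}

#' Maximum voluntary contraction value
#'
#' Processes each MVC trial (high-pass, rectify, low-pass smooth) and
#' returns the maximum of the smoothed envelope over all trials — the
#' normalization constant for the excitation signal.
#'
#' @param trials A list of raw [emg_trace()] objects (>= 1), or a single
#'   trace.
#' @param config An [emg_config()].
#' @return The MVC value (> 0), in the voltage units of the raw signal.
#' @export
compute_mvc <- function(trials, config = emg_config()) {
  if (inherits(trials, "emg_trace")) trials <- list(trials)
  if (length(trials) < 1L) abort("Need at least one MVC trial.")
  peaks <- vapply(trials, function(tr) {
    env <- tr |>
      highpass_filter(config$highpass_hz, config$highpass_order) |>
      rectify() |>
      lowpass_smooth(config$lowpass_hz, config$lowpass_order)
    max(trace_samples(env))
  }, numeric(1))
  mvc <- max(peaks)
  if (mvc <= 0) abort("Degenerate MVC: all trials have zero envelope.")
  mvc
}

#' Normalize a trace by the MVC value
#'
#' Divides the samples by `mvc_value` and clamps values above 1 to 1.
#'
#' @param u An [emg_trace()].
#' @param mvc_value MVC normalization constant (> 0).
#' @return The normalized trace at the same stage.
#' @export
normalize_mvc <- function(u, mvc_value) {
  if (!is.numeric(mvc_value) || length(mvc_value) != 1L || mvc_value <= 0) {
    abort("`mvc_value` must be a single positive number.")
  }
  retrace(u, pmin(trace_samples(u) / mvc_value, 1), emg_stage(u))
}

#' Dead-band value rectification
#'
#' Suppresses small sample-to-sample drifts in the activation level with
#' staircase semantics: the output holds its previous value until the input
#' moves away from that held value by more than the band, at which point the
#' new value passes through unchanged and becomes the new held value. The
#' band is relative to the current held value, with an absolute floor of
#' `dead_band` for held values below `dead_band` so that the relaxation
#' state stays pinned near zero. The empirical band range is 1-3 % of the
#' activation scale.
#'
#' @param a An [emg_trace()] at stage `"activation"` (a bare numeric vector
#'   is also accepted and returned).
#' @param dead_band Relative band, in \[0.01, 0.03\].
#' @return The rectified activation, same type as the input.
#' @export
dead_band_rectify <- function(a, dead_band = 0.02) {
  if (dead_band < 0.01 || dead_band > 0.03) {
    abort("`dead_band` must lie in [0.01, 0.03].")
  }
  x <- if (inherits(a, "emg_trace")) trace_samples(a) else a
  y <- dead_band_core(x, dead_band)
  if (inherits(a, "emg_trace")) retrace(a, y, "activation") else y
}

dead_band_core <- function(x, dead_band) {
  n <- length(x)
  y <- numeric(n)
  held <- x[1L]
  y[1L] <- held
  for (i in seq_len(n - 1L) + 1L) {
    band <- if (abs(held) < dead_band) dead_band else dead_band * abs(held)
    if (abs(x[i] - held) > band) held <- x[i]
    y[i] <- held
  }
  y
}

#' Full EMG-to-activation processing chain
#'
#' Convenience wrapper running high-pass, rectification, activation
#' dynamics, low-pass smoothing, MVC normalization and the activation
#' nonlinearity in sequence. The dead-band value rectification is *not*
#' applied here; it belongs to the state-machine input (see
#' [run_state_machine()]), and calibration uses the smooth activation.
#'
#' @param trace A raw [emg_trace()], or a tibble with `time_s` and `emg`
#'   columns (e.g. from [read_emg_csv()]).
#' @param mvc_value MVC normalization constant from [compute_mvc()].
#' @param config An [emg_config()].
#' @return An activation trace at stage `"activation"`, values in \[0, 1\].
#' @export
process_emg <- function(trace, mvc_value, config = emg_config()) {
  if (!inherits(trace, "emg_trace")) {
    fs <- attr(trace, "sampling_rate", exact = TRUE)
    if (is.null(fs)) fs <- 1 / stats::median(diff(trace$time_s))
    trace <- emg_trace(trace$emg, fs, stage = "raw", time_s = trace$time_s)
  }
  fs <- sampling_rate(trace)
  coeffs <- make_filter_coefficients(
    config$gamma1, config$gamma2,
    delay_samples = round(config$delay_s * fs)
  )
  trace |>
    highpass_filter(config$highpass_hz, config$highpass_order) |>
    rectify() |>
    activation_dynamics(coeffs) |>
    lowpass_smooth(config$lowpass_hz, config$lowpass_order) |>
    normalize_mvc(mvc_value) |>
    activation_nonlinearity(A = config$A, R = config$R)
}

check_cutoff <- function(cutoff_hz, fs) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort(sprintf(
      "Cutoff must lie strictly between 0 and the Nyquist frequency (%g Hz).",
      fs / 2
    ))
  }
}
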