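#' Four-state switching model
#'
#' The activation-to-angle map fitted during calibration only describes the
#' concentric flexion phase. Over a whole movement the muscle passes through
#' four regimes — relaxation, flexion (concentric), holding (isometric) and
#' extension (active shortening) — and the activation level carries a
#' transient excess ("overshoot") at the flexion-to-holding transition
#' because the acceleration torque disappears when the arm stops. The state
#' machine selects, per sample, how activation is converted to angle:
#'
#' * **relaxation** outputs 0 degrees; a rising trend above the inactivation
#'   level starts flexion.
#' * **flexion** outputs the inverse calibration map and tracks the last
#'   flexion angle `theta_max`; when the activation stops increasing while
#'   above the holding threshold, holding begins; when it is falling while
#'   at or below `holding_threshold * (1 - dead_band)` (no hold is
#'   imminent), extension begins directly, continuously (the gain is ~1
#'   there because consecutive flexion outputs are adjacent).
#' * **holding** outputs `theta_max` frozen (zero-order hold); extension
#'   begins as soon as the activation is classified falling. The
#'   flexion-overshoot relaxation typically triggers this shortly after the
#'   hold starts, which is benign: the extension state with a flat trend
#'   outputs `p * invert_map(a)` anchored at the held angle by the
#'   continuity gain, so the output keeps holding until the activation
#'   genuinely decays. The dead band and the trend hysteresis set the
#'   detection latency of a genuine decrease (see [predicted_time_lag()]).
#' * **extension** outputs `p * invert_map(a)` clamped to \[0, 90\], where
#'   the proportional gain `p = theta_max / theta_prime_max` splices the
#'   extension branch continuously onto the held angle
#'   (`theta_prime_max` is the inverse-map angle at the first extension
#'   sample). Activation falling to the inactivation level returns to
#'   relaxation; a rising trend re-enters flexion.
#'
#' @name state_machine
NULL

#' Create a switching-model state
#'
#' @param name One of `"relaxation"`, `"flexion"`, `"holding"`,
#'   `"extension"`.
#' @param theta_max Last angle of the flexion state, degrees.
#' @param theta_prime_max Inverse-map angle at the first extension sample,
#'   degrees.
#' @param p Proportional gain for the extension state.
#' @param a_min Running minimum of the activation over the current
#'   extension episode (the Schmitt-trigger reference for re-flexion).
#' @return A list of class `switch_state`.
#' @export
switch_state <- function(name = "relaxation", theta_max = 0,
                         theta_prime_max = NA_real_, p = 1,
                         a_min = NA_real_) {
  name <- match.arg(name, c("relaxation", "flexion", "holding", "extension"))
  structure(list(name = name, theta_max = theta_max,
                 theta_prime_max = theta_prime_max, p = p, a_min = a_min,
                 flat_run = 0L),
            class = "switch_state")
}

#' One step of the switching model
#'
#' Advances the state machine by one sample. See [state_machine] for the
#' transition rules.
#'
#' @param state A [switch_state()].
#' @param a_t Activation level at this sample, in \[0, 1\].
#' @param trend One of `"rising"`, `"flat"`, `"falling"`.
#' @param model A fitted `calibration_model`.
#' @param p_max Saturation for the proportional gain when
#'   `theta_prime_max` is (near) zero at extension entry.
#' @param hold_dwell Number of consecutive non-rising samples required in
#'   flexion before the holding state can be entered (debouncing: a single
#'   flat-classified sample during a noisy ramp must not freeze the hold
#'   angle early); 0 disables the dwell.
#' @return A list with elements `state` (the updated [switch_state()]) and
#'   `theta` (the output angle in degrees).
#' @export
step_state <- function(state, a_t, trend, model, p_max = 3, hold_dwell = 0) {
  stopifnot(inherits(state, "switch_state"))
  trend <- match.arg(trend, c("rising", "flat", "falling"))
  exit_level <- model$holding_threshold * (1 - model$dead_band)
  state$flat_run <- if (trend == "rising") 0L else state$flat_run + 1L

  if (state$name == "relaxation") {
    if (trend == "rising" && a_t > model$inactivation_level) {
      state$name <- "flexion"
      state$p <- 1
      state$theta_max <- invert_map(a_t, model)
      return(list(state = state, theta = state$theta_max))
    }
    return(list(state = state, theta = 0))
  }

  if (state$name == "flexion") {
    theta <- invert_map(a_t, model)
    if (trend %in% c("flat", "falling") && a_t > model$holding_threshold &&
        state$flat_run > hold_dwell) {
      state$theta_max <- theta
      state$name <- "holding"
      return(list(state = state, theta = state$theta_max))
    }
    if (trend == "falling" && a_t <= exit_level) {
      # below the holding band the activation is already decreasing:
      # extension directly; continuity gives p ~= 1 here
      state$name <- "extension"
      state$theta_prime_max <- theta
      state$a_min <- a_t
      state$p <- proportional_gain(state$theta_max, state$theta_prime_max,
                                   p_max = p_max)
      return(list(state = state, theta = clamp(state$p * theta, 0, 90)))
    }
    state$theta_max <- theta
    return(list(state = state, theta = theta))
  }

  if (state$name == "holding") {
    if (trend == "rising") {
      # activation still climbing: the flexion had not actually ended, so
      # the held angle ratchets up with the map (never down)
      state$theta_max <- max(state$theta_max, invert_map(a_t, model))
      return(list(state = state, theta = state$theta_max))
    }
    if (trend == "falling") {
      state$name <- "extension"
      state$theta_prime_max <- invert_map(a_t, model)
      state$a_min <- a_t
      state$p <- proportional_gain(state$theta_max, state$theta_prime_max,
                                   p_max = p_max)
      theta <- clamp(state$p * state$theta_prime_max, 0, 90)
      return(list(state = state, theta = theta))
    }
    return(list(state = state, theta = state$theta_max))
  }

  # extension
  if (a_t <= model$inactivation_level) {
    state$name <- "relaxation"
    return(list(state = state, theta = 0))
  }
  state$a_min <- min(state$a_min, a_t, na.rm = TRUE)
  if (trend == "rising" && a_t > state$a_min + 2 * model$dead_band) {
    # re-flexion only on a rise clearly above the episode minimum
    # (Schmitt trigger: jitter around a plateau must not flip the state)
    state$name <- "flexion"
    theta <- invert_map(a_t, model)
    state$theta_max <- theta
    return(list(state = state, theta = theta))
  }
  theta <- clamp(state$p * invert_map(a_t, model), 0, 90)
  list(state = state, theta = theta)
}

#' Proportional gain for the extension state
#'
#' `p = theta_max / theta_prime_max`, the ratio of the held angle to the
#' inverse-map angle at extension entry. The gain rescales the extension
#' branch of the map so that the output is continuous across the
#' holding-to-extension boundary. A (near) zero `theta_prime_max` saturates
#' the gain at `p_max` with a warning.
#'
#' @param theta_max Angle at the end of the flexion state, degrees.
#' @param theta_prime_max Inverse-map angle at the beginning of the
#'   extension state, degrees.
#' @param p_max Gain saturation.
#' @return The gain `p` (> 0).
#' @export
proportional_gain <- function(theta_max, theta_prime_max, p_max = 3) {
  if (!is.finite(theta_prime_max) || theta_prime_max <= 0) {
    warn("theta_prime_max <= 0 at extension entry; gain saturated at p_max.")
    return(p_max)
  }
  min(theta_max / theta_prime_max, p_max)
}

#' Predicted switching time lag
#'
#' When a flexion is immediately followed by an extension (no hold), the
#' model must still pass through the holding state, and the output stays
#' frozen until the activation falls from its peak `F_p` to
#' `F_t * (1 - a_r)`, where `F_t` is the holding threshold and `a_r` the
#' dead band. With activation decreasing at rate `gamma` (activation units
#' per second), the lag is `t_lag = (F_p - F_t * (1 - a_r)) / gamma`.
#' Diagnostic only; the control path never uses it.
#'
#' @param F_p Peak activation level.
#' @param F_t Holding threshold.
#' @param a_r Dead band (relative).
#' @param gamma Activation decrease rate, per second (> 0).
#' @return Lag in seconds.
#' @export
predicted_time_lag <- function(F_p, F_t, a_r, gamma) {
  if (gamma <= 0) abort("`gamma` must be > 0.")
  (F_p - F_t * (1 - a_r)) / gamma
}

#' Classify the activation trend per sample
#'
#' Least-squares slope of the activation over a trailing sliding window;
#' the trend is `"flat"` when the predicted change across the window
#' (`slope * window duration`) is within `hysteresis`, otherwise
#' `"rising"`/`"falling"` by sign. The first `window - 1` samples, where no
#' full window exists, are classified flat (traces start at rest).
#'
#' @param a Activation samples (numeric vector).
#' @param sampling_rate Sampling rate, Hz.
#' @param window_s Window duration, seconds (>= 2 samples).
#' @param hysteresis Flat band, activation units.
#' @return A character vector of `"rising"`, `"flat"`, `"falling"`.
#' @export
classify_trend <- function(a, sampling_rate, window_s = 0.25,
                           hysteresis = 0.02) {
  w <- max(2L, round(window_s * sampling_rate))
  n <- length(a)
  # trailing-window least-squares slope via a linear filter:
  # slope_t = sum_k c_k a[t - w + k], c_k proportional to (k - mean(k))
  k <- seq_len(w)
  ck <- (k - mean(k)) / sum((k - mean(k))^2) * sampling_rate
  slope <- as.numeric(stats::filter(a, rev(ck), sides = 1))
  slope[seq_len(min(w - 1L, n))] <- 0
  change <- slope * (w / sampling_rate)
  out <- rep("flat", n)
  out[change > hysteresis] <- "rising"
  out[change < -hysteresis] <- "falling"
  out
}

#' Run the switching model over an activation trace
#'
#' Applies the dead-band value rectification, classifies the per-sample
#' trend, and iterates [step_state()] over the trace. The output is
#' continuous across the holding-to-extension boundary by construction of
#' the proportional gain. Batch and streaming use agree exactly: the
#' computation is strictly causal, so the output over any prefix equals the
#' prefix of the full output.
#'
#' @param a An activation [emg_trace()] (stage `"activation"`) or a tibble
#'   with `time_s` and `activation` columns.
#' @param model A fitted `calibration_model`.
#' @param config An [emg_config()]; supplies the dead band, trend window,
#'   hysteresis and `p_max`.
#' @return A tibble with columns `time_s`, `activation` (dead-banded),
#'   `trend`, `state` and `angle_deg`, of class `emg_prediction`.
#' @export
run_state_machine <- function(a, model, config = emg_config()) {
  stopifnot(inherits(model, "calibration_model"))
  if (inherits(a, "emg_trace")) {
    check_stage(a, "activation", "run_state_machine")
    fs <- sampling_rate(a)
    act <- trace_samples(a)
    time_s <- a$time_s
  } else {
    act <- a$activation
    time_s <- a$time_s
    fs <- 1 / median(diff(time_s))
  }
  adb <- dead_band_core(act, config$dead_band)
  trend <- classify_trend(adb, fs, config$trend_window_s,
                          config$trend_hysteresis)
  n <- length(adb)
  states <- character(n)
  theta <- numeric(n)
  st <- switch_state("relaxation")
  dwell <- round(config$hold_dwell_s * fs)
  for (i in seq_len(n)) {
    res <- step_state(st, adb[i], trend[i], model, p_max = config$p_max,
                      hold_dwell = dwell)
    st <- res$state
    states[i] <- st$name
    theta[i] <- res$theta
  }
  structure(
    tibble(time_s = time_s, activation = adb, trend = trend,
           state = states, angle_deg = theta),
    class = c("emg_prediction", class(tibble())),
    sampling_rate = fs
  )
}
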