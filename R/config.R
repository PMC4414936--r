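#' Processing configuration
#'
#' Collects every tunable of the signal-processing chain and the state
#' machine in one flat list, with physiologically motivated defaults:
#' a 4th-order 10 Hz high-pass on the raw EMG, a 2nd-order 1 Hz low-pass
#' on the neural excitation (the top of the useful 0.5-1 Hz range: the
#' causal low-pass dominates the chain's group delay, and a lower cutoff
#' doubles back as extension-phase over-prediction), recursive
#' activation-dynamics poles `gamma1 = gamma2 = -0.5`, a zero
#' electromechanical delay (set `delay_s` to the subject's 30-100 ms delay
#' for real recordings), the
#' exponential activation nonlinearity with shape `A = 1` (mild curvature,
#' so the activation-to-angle relation stays quadratic-like) and scaling
#' `R = 1/A` (so MVC-normalized excitation in \[0, 1\] maps onto activation
#' in \[0, 1\]), a 2 % dead band, a holding threshold at fraction
#' `kappa = 0.9` of the calibration holding plateau, a 250 ms trend window
#' and a proportional-gain saturation `p_max = 3`.
#'
#' @param highpass_hz High-pass cutoff for raw EMG, Hz.
#' @param highpass_order High-pass Butterworth order.
#' @param lowpass_hz Low-pass cutoff for the excitation envelope, Hz
#'   (the useful range is about 0.5-1 Hz; lower is smoother but laggier).
#' @param lowpass_order Low-pass Butterworth order.
#' @param gamma1,gamma2 Recursive poles of the activation dynamics,
#'   `|gamma| < 1`.
#' @param delay_s Electromechanical delay in seconds.
#' @param A Activation nonlinearity shape parameter (> 0).
#' @param R Excitation scaling of the nonlinearity; default `1/A`.
#' @param dead_band Relative dead band for the value-rectification filter,
#'   in \[0.01, 0.03\].
#' @param kappa Holding threshold as a fraction of the activation plateau
#'   measured over the calibration hold (falling back to the flexion peak
#'   when the calibration trial has no hold).
#' @param trend_window_s Sliding window for trend classification, seconds.
#' @param trend_hysteresis Activation change across the trend window below
#'   which the trend is classified flat; defaults to `dead_band`.
#' @param hold_dwell_s Time the trend must stay non-rising in flexion
#'   before holding can be entered, seconds (debounces trend blips during
#'   a noisy ramp).
#' @param p_max Saturation for the extension proportional gain.
#'
#' @return A named list of class `emg_config`.
#' @export
emg_config <- function(highpass_hz = 10, highpass_order = 4,
                       lowpass_hz = 1.0, lowpass_order = 2,
                       gamma1 = -0.5, gamma2 = -0.5,
                       delay_s = 0,
                       A = 1, R = 1 / A,
                       dead_band = 0.02,
                       kappa = 0.9,
                       trend_window_s = 0.25,
                       trend_hysteresis = dead_band,
                       hold_dwell_s = 0.15,
                       p_max = 3) {
  cfg <- list(
    highpass_hz = highpass_hz, highpass_order = highpass_order,
    lowpass_hz = lowpass_hz, lowpass_order = lowpass_order,
    gamma1 = gamma1, gamma2 = gamma2, delay_s = delay_s,
    A = A, R = R, dead_band = dead_band, kappa = kappa,
    trend_window_s = trend_window_s, trend_hysteresis = trend_hysteresis,
    hold_dwell_s = hold_dwell_s, p_max = p_max
  )
  if (abs(gamma1) >= 1 || abs(gamma2) >= 1) {
    abort("Activation-dynamics poles must satisfy |gamma| < 1.")
  }
  if (A <= 0) abort("`A` must be > 0.")
  if (R <= 0) abort("`R` must be > 0.")
  if (dead_band < 0.01 || dead_band > 0.03) {
    abort("`dead_band` must lie in [0.01, 0.03].")
  }
  if (kappa <= 0 || kappa >= 1) abort("`kappa` must lie in (0, 1).")
  structure(cfg, class = c("emg_config", "list"))
}

#' Read or write a configuration file
#'
#' Configurations are stored as a flat key-value file, JSON
#' (`.json`) or YAML (`.yml`/`.yaml`), holding the arguments of
#' [emg_config()]. Unknown keys raise an error.
#'
#' @param path File path; format chosen by extension.
#' @return `read_emg_config()` returns an `emg_config`.
#' @export
read_emg_config <- function(path) {
  vals <- read_flat_file(path)
  known <- names(formals(emg_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0L) {
    abort(sprintf("%s: unknown config keys: %s", path,
                  paste(extra, collapse = ", ")))
  }
  do.call(emg_config, vals)
}

#' @rdname read_emg_config
#' @param config An `emg_config`.
#' @export
write_emg_config <- function(config, path) {
  write_flat_file(unclass(config), path)
}

read_flat_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_flat_file <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
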