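#' Root-mean-square error between angle series
#'
#' @param pred Predicted angles, degrees.
#' @param truth Reference angles, degrees, same length.
#' @return `sqrt(mean((pred - truth)^2))`, degrees.
#' @export
rms_error <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have the same length.")
  }
  if (length(pred) < 1L) abort("Need at least one sample.")
  sqrt(mean((pred - truth)^2))
}

#' Pearson correlation between angle series
#'
#' @param pred Predicted angles.
#' @param truth Reference angles, same length.
#' @return Pearson r in \[-1, 1\].
#' @export
angle_correlation <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have the same length.")
  }
  if (sd(pred) == 0 || sd(truth) == 0) {
    abort("Correlation undefined: a series has zero variance.")
  }
  cor(pred, truth)
}

#' Run the full prediction pipeline on one trial
#'
#' Processes raw EMG through the activation chain ([process_emg()]) and the
#' switching model ([run_state_machine()]).
#'
#' @param trial A tibble with columns `time_s`, `emg` (e.g. from
#'   [read_emg_csv()] or [generate_dataset()]), or a raw [emg_trace()].
#' @param model A fitted `calibration_model`.
#' @param mvc_value MVC normalization constant.
#' @param config An [emg_config()].
#' @return An `emg_prediction` tibble with columns `time_s`, `activation`,
#'   `trend`, `state`, `angle_deg`.
#' @export
predict_angles <- function(trial, model, mvc_value, config = emg_config()) {
  act <- process_emg(trial, mvc_value, config)
  run_state_machine(act, model, config)
}

#' Evaluate a prediction against ground truth
#'
#' @param pred An `emg_prediction` from [predict_angles()] (or any tibble
#'   with `time_s`, `angle_deg` and optionally `state`).
#' @param truth Ground-truth angles: a numeric vector or a tibble with an
#'   `angle_deg` column, same length.
#' @return An `evaluation_report`: a one-row tibble with `rms_error`
#'   (degrees), `correlation`, `lag_s` (cross-correlation peak lag,
#'   positive when the prediction trails the truth) and `n`; per-state RMS
#'   errors are attached and available via [tidy.evaluation_report()].
#' @export
evaluate_prediction <- function(pred, truth) {
  tv <- if (is.data.frame(truth)) truth$angle_deg else truth
  pv <- pred$angle_deg
  if (length(pv) != length(tv)) {
    abort("Prediction and truth must have the same length.")
  }
  fs <- attr(pred, "sampling_rate", exact = TRUE)
  if (is.null(fs)) fs <- 1 / median(diff(pred$time_s))
  lag_s <- if (sd(pv) > 0 && sd(tv) > 0) {
    cc <- stats::ccf(pv, tv, lag.max = round(fs), plot = FALSE)
    cc$lag[which.max(cc$acf)] / fs
  } else {
    NA_real_
  }
  per_state <- if ("state" %in% names(pred)) {
    tibble(state = pred$state, err = pv - tv) |>
      dplyr::group_by(.data$state) |>
      dplyr::summarise(rms_error = sqrt(mean(.data$err^2))) |>
      (\(d) stats::setNames(d$rms_error, d$state))()
  } else {
    NULL
  }
  structure(
    tibble(
      rms_error = rms_error(pv, tv),
      correlation = if (sd(pv) > 0 && sd(tv) > 0) cor(pv, tv) else NA_real_,
      lag_s = lag_s,
      n = length(pv)
    ),
    per_state_rms = per_state,
    class = c("evaluation_report", class(tibble()))
  )
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A tibble with one row per state and its RMS error.
#' @export
tidy.evaluation_report <- function(x, ...) {
  ps <- attr(x, "per_state_rms", exact = TRUE)
  if (is.null(ps)) return(tibble(state = character(), rms_error = numeric()))
  tibble(state = names(ps), rms_error = unname(ps))
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) as_tibble(x)
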