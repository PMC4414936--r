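#' Plot an EMG trace
#'
#' @param object An [emg_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.emg_trace <- function(object, ...) {
  col <- if (identical(emg_stage(object), "activation")) "activation"
         else "emg"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data[[col]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = if (col == "activation") "muscle activation" else "EMG (a.u.)",
      title = sprintf("EMG trace (stage: %s)", emg_stage(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' Shows the fitted quadratic activation-to-`cos^2(theta)` map over the
#' observed calibration range.
#'
#' @param object A `calibration_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_model <- function(object, ...) {
  a <- seq(0, object$peak_activation, length.out = 200)
  df <- tibble(
    activation = a,
    cos2_theta = clamp(quadratic_model_value(a, object$poly_coeffs,
                                             object$R), 0, 1),
    angle_deg = invert_map(a, object)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$activation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cos2_theta)) +
    ggplot2::labs(
      x = "muscle activation a",
      y = expression(cos^2 * theta),
      title = sprintf("Calibration map (fit r = %.3f)", object$fit_r)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a prediction
#'
#' Predicted elbow angle over time, coloured by switching-model state; a
#' ground-truth series can be overlaid.
#'
#' @param object An `emg_prediction` from [predict_angles()].
#' @param truth Optional ground-truth angles (numeric vector or tibble
#'   with `angle_deg`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.emg_prediction <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$angle_deg))
  if (!is.null(truth)) {
    tv <- if (is.data.frame(truth)) truth$angle_deg else truth
    p <- p + ggplot2::geom_line(
      data = tibble(time_s = object$time_s, angle_deg = tv),
      colour = "grey50", linetype = "dashed"
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(colour = .data$state, group = 1)) +
    ggplot2::labs(x = "time (s)", y = "elbow angle (degrees)",
                  colour = "state") +
    ggplot2::theme_minimal()
}
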