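#' Hill-type muscle model parameters
#'
#' Parameters of the lumped Hill-type musculotendon model of the biceps
#' brachii used to derive the activation-to-angle relationship. The tendon
#' is assumed rigid (no series element) and the parallel elastic element,
#' while implemented, contributes zero force in the pipeline for voluntary
#' sagittal-plane flexion/extension.
#'
#' @param F_max Maximum isometric force, N.
#' @param L_CE0 Optimal contractile-element length, m.
#' @param V_CE_max Maximum contraction velocity in units of `L_CE0` per
#'   second; 10 is the accepted value for upper-limb muscles.
#' @param alpha_ratio Ratio of the tendon-insertion distance `l` to the
#'   forearm-centroid distance `L`, in (0, 1).
#' @param S Passive-element shape parameter (non-zero).
#' @param dL_max Passive-element maximum length change, m.
#' @return A list of class `hill_parameters`.
#' @export
hill_parameters <- function(F_max = 300, L_CE0 = 0.12, V_CE_max = 10,
                            alpha_ratio = 0.1, S = 1, dL_max = 0.05) {
  if (F_max <= 0 || L_CE0 <= 0 || V_CE_max <= 0 || dL_max <= 0) {
    abort("`F_max`, `L_CE0`, `V_CE_max` and `dL_max` must be > 0.")
  }
  if (alpha_ratio <= 0 || alpha_ratio >= 1) {
    abort("`alpha_ratio` must lie in (0, 1).")
  }
  if (S == 0) abort("`S` must be non-zero.")
  structure(
    list(F_max = F_max, L_CE0 = L_CE0, V_CE_max = V_CE_max,
         alpha_ratio = alpha_ratio, S = S, dL_max = dL_max),
    class = "hill_parameters"
  )
}

#' Passive element force
#'
#' Exponential passive force-length relation
#' `F = (F_max / exp(S) - 1) * (exp((S / dL_max) * delta_L) - 1)`,
#' zero at zero length change. Present for completeness: the pipeline wires
#' the passive contribution to zero.
#'
#' @param delta_L Length change relative to slack length, m.
#' @param params A [hill_parameters()] object.
#' @return Passive force, N.
#' @export
passive_force <- function(delta_L, params = hill_parameters()) {
  (params$F_max / exp(params$S) - 1) *
    (exp((params$S / params$dL_max) * delta_L) - 1)
}

#' Active force-length relation
#'
#' Gaussian force-length factor
#' `f_l = exp(-0.5 * ((delta_L_CE / L_CE0 - 0.05) / 0.19)^2)`, maximal
#' (exactly 1) at a relative length change of 0.05.
#'
#' @param delta_L_CE Contractile-element length change, m.
#' @param L_CE0 Optimal contractile-element length, m.
#' @return Dimensionless factor in (0, 1].
#' @export
force_length <- function(delta_L_CE, L_CE0 = 1) {
  if (L_CE0 <= 0) abort("`L_CE0` must be > 0.")
  exp(-0.5 * ((delta_L_CE / L_CE0 - 0.05) / 0.19)^2)
}

#' Force-velocity relation
#'
#' `f_v = 0.1433 / (0.1074 + exp(-1.3 * sinh(2.8 * v_ratio + 1.64)))` where
#' `v_ratio = V_CE / V_CE0` (negative for concentric shortening). Monotone
#' increasing, with limits 0 as `v_ratio -> -Inf` and
#' `0.1433 / 0.1074 ~= 1.334` as `v_ratio -> +Inf`. The `sinh` argument is
#' saturated at |30| to return the analytic asymptote instead of
#' overflowing.
#'
#' @param v_ratio Contraction velocity over the activation-scaled maximum
#'   velocity (dimensionless, finite).
#' @return Dimensionless factor in (0, 1.334].
#' @export
force_velocity <- function(v_ratio) {
  arg <- 2.8 * v_ratio + 1.64
  s <- ifelse(abs(arg) > 30, sign(arg) * sinh(30), sinh(arg))
  e <- exp(pmin(-1.3 * s, 700))  # avoid Inf * 0 edge cases
  0.1433 / (0.1074 + e)
}

#' Activation-scaled maximum contraction velocity
#'
#' `V_CE0 = 0.5 * (a + 1) * V_CE_max`: the velocity scale grows linearly
#' from half the maximum (passive muscle) to the full maximum (fully
#' activated).
#'
#' @param a Activation level in \[0, 1\].
#' @param params A [hill_parameters()] object.
#' @return Velocity in `L_CE0` units per second.
#' @export
vce0 <- function(a, params = hill_parameters()) {
  if (any(a < 0 | a > 1)) abort("`a` must lie in [0, 1].")
  0.5 * (a + 1) * params$V_CE_max
}

#' Contractile element force at a joint state
#'
#' `F_CE = F_max * a * f_l * f_v` with the geometry of the elbow model:
#' the contractile length change is `alpha_ratio * L_CE0 * cos(theta)` and
#' the normalized contraction velocity is
#' `-0.1 * alpha_ratio * theta_dot * sin(theta)` with `theta_dot` in rad/s
#' (degrees are accepted at the interface and converted internally, since
#' the derivative of `l cos(theta)` requires radians). The angle convention
#' is `theta = 0` at full extension and 90 degrees with the forearm
#' horizontal, so `cos(theta)` falls from 1 to 0 with flexion.
#'
#' @param a Activation in \[0, 1\].
#' @param theta Elbow angle, degrees in \[0, 90\].
#' @param dtheta Angular velocity, degrees per second.
#' @param params A [hill_parameters()] object.
#' @return Contractile force, N.
#' @export
contractile_force <- function(a, theta, dtheta = 0,
                              params = hill_parameters()) {
  if (any(a < 0 | a > 1)) abort("`a` must lie in [0, 1].")
  th <- deg2rad(theta)
  dL <- params$alpha_ratio * params$L_CE0 * cos(th)
  v_ratio <- -0.1 * params$alpha_ratio * deg2rad(dtheta) * sin(th)
  params$F_max * a * force_length(dL, params$L_CE0) * force_velocity(v_ratio)
}

#' Total musculotendon force
#'
#' `F_T = F_CE + F_PE`. In this pipeline the passive contribution is zero.
#'
#' @param F_CE Contractile force, N.
#' @param F_PE Passive force, N.
#' @return Total force, N.
#' @export
total_force <- function(F_CE, F_PE = 0) {
  if (!all(is.finite(F_CE)) || !all(is.finite(F_PE))) {
    abort("Forces must be finite.")
  }
  F_CE + F_PE
}

#' Quadratic model value
#'
#' Evaluates `sum_i a_i * (a / R)^i` for `i = 0..2` — the quadratic
#' polynomial structure used by the calibration to represent the
#' activation-to-cos-squared-angle relationship with all lumped constants
#' absorbed into the fitted coefficients.
#'
#' @param a Activation value(s).
#' @param coefficients Numeric vector `(a0, a1, a2)`.
#' @param R Excitation scaling used in the fit.
#' @return The polynomial value(s).
#' @export
quadratic_model_value <- function(a, coefficients, R = 1) {
  stopifnot(length(coefficients) == 3L)
  x <- a / R
  coefficients[1L] + coefficients[2L] * x + coefficients[3L] * x^2
}
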