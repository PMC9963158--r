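# Modified stretched-exponential (MSE) enthalpy-relaxation model.
#
# The relaxation survival function is
#   Phi(t) = exp[ -(t/tau0) * (1 + t/tau1)^(beta - 1) ]
# and the exothermic heat flow of a relaxing glass is its time derivative,
#   P(t) = 277.8 * (dHr_inf/tau0) * (1 + beta*t/tau1) * (1 + t/tau1)^(beta-2)
#          * Phi(t)   [microwatt per gram],
# i.e. P = -277.8 * dHr_inf * dPhi/dt exactly. Time is in hours throughout;
# the constant 277.8 converts J/(g*h) to uW/g (1e6/3600, rounded as printed
# in the thermal-analysis literature).

#' Conversion constant from J/(g h) to uW/g used by the MSE power model
#'
#' @format A length-one numeric, 277.8.
#' @export
mse_power_constant <- 277.8

#' MSE relaxation parameters
#'
#' Constructs and validates the parameter triple of the modified
#' stretched-exponential relaxation model: the primary relaxation time
#' `tau0`, the crossover time `tau1` (both in hours) and the stretch
#' exponent `beta`. The model constraints are `tau0 > tau1 > 0` and
#' `0 < beta <= 1`.
#'
#' @param tau0 Primary relaxation time in hours; must exceed `tau1`.
#' @param tau1 Crossover time in hours; must be positive.
#' @param beta Stretch exponent, in (0, 1].
#'
#' @return An object of class `mse_params`.
#' @examples
#' mse_params(2, 1, 0.1)  # conventional fit start values
#' @export
mse_params <- function(tau0, tau1, beta) {
  stopifnot(is.numeric(tau0), is.numeric(tau1), is.numeric(beta),
            length(tau0) == 1L, length(tau1) == 1L, length(beta) == 1L)
  if (!is.finite(tau0) || !is.finite(tau1) || !is.finite(beta))
    stop("MSE parameters must be finite")
  if (tau1 <= 0) stop("tau1 must be positive")
  if (tau0 <= tau1) stop("constraint violated: tau0 > tau1 required (got tau0 = ",
                         format(tau0), ", tau1 = ", format(tau1), ")")
  if (beta <= 0 || beta > 1) stop("constraint violated: 0 < beta <= 1 required")
  structure(list(tau0 = as.numeric(tau0), tau1 = as.numeric(tau1),
                 beta = as.numeric(beta)),
            class = "mse_params")
}

#' @export
print.mse_params <- function(x, ...) {
  cat(sprintf("MSE parameters: tau0 = %.6g h, tau1 = %.6g h, beta = %.6g\n",
              x$tau0, x$tau1, x$beta))
  invisible(x)
}

#' Thermal context of a relaxation measurement
#'
#' Bundles the measurement (or storage) temperature, the glass-transition
#' midpoint, the heat-capacity step at Tg and the derived maximum
#' recoverable relaxation enthalpy `dHr_inf = (Tg - T) * delta_cp`, the
#' amplitude of the relaxation signal.
#'
#' @param temperature Measurement/storage temperature in degrees Celsius.
#' @param tg Glass-transition midpoint in degrees Celsius.
#' @param delta_cp Heat-capacity step at Tg in J/(g K); must be positive.
#'
#' @return An object of class `thermal_context` with fields `temperature`,
#'   `tg`, `delta_cp` and `delta_h_r_inf` (J/g).
#' @examples
#' thermal_context(temperature = 25, tg = 60.21, delta_cp = 0.5)
#' @export
thermal_context <- function(temperature, tg, delta_cp) {
  h <- delta_h_r_inf(temperature, tg, delta_cp)
  structure(list(temperature = as.numeric(temperature), tg = as.numeric(tg),
                 delta_cp = as.numeric(delta_cp), delta_h_r_inf = h),
            class = "thermal_context")
}

#' @export
print.thermal_context <- function(x, ...) {
  cat(sprintf("Thermal context: T = %.4g degC, Tg = %.4g degC, dcp = %.4g J/(g K), dHr_inf = %.6g J/g\n",
              x$temperature, x$tg, x$delta_cp, x$delta_h_r_inf))
  invisible(x)
}

#' Maximum recoverable relaxation enthalpy
#'
#' Computes `dHr_inf = (Tg - T) * delta_cp`, the maximum enthalpy a glass
#' stored at temperature `T` below its glass transition `Tg` can recover by
#' structural relaxation. This is the fixed amplitude of the MSE power model.
#' Samples at or above Tg are outside the model's domain (no glassy
#' relaxation), so `temperature > tg` is an error.
#'
#' @param temperature Storage/measurement temperature, degrees Celsius.
#' @param tg Glass-transition midpoint, degrees Celsius.
#' @param delta_cp Heat-capacity step at Tg, J/(g K); positive.
#'
#' @return Enthalpy in J/g, `>= 0`; zero exactly when `temperature == tg`.
#' @examples
#' delta_h_r_inf(25, 60.21, 0.5)    # 17.605 J/g
#' delta_h_r_inf(40, 104.46, 0.4)   # 25.784 J/g
#' @export
delta_h_r_inf <- function(temperature, tg, delta_cp) {
  stopifnot(is.numeric(temperature), is.numeric(tg), is.numeric(delta_cp))
  if (any(delta_cp <= 0)) stop("delta_cp must be positive")
  if (any(temperature > tg))
    stop("temperature above Tg: relaxation model not applicable")
  (tg - temperature) * delta_cp
}

#' MSE relaxation survival function
#'
#' Evaluates `Phi(t) = exp[-(t/tau0) * (1 + t/tau1)^(beta - 1)]`, the
#' fraction of relaxation enthalpy not yet released at time `t`. `Phi` is 1
#' at `t = 0`, strictly decreasing, and tends to 0; for `t >> tau1` it
#' approaches the Kohlrausch-Williams-Watts form `exp[-(t/tau)^beta]` with
#' `tau^beta = tau0 * tau1^(beta-1)`.
#'
#' @param t Time in hours, `>= 0`; vectorised.
#' @param params An [mse_params] object.
#'
#' @return Numeric vector of survival fractions in (0, 1].
#' @examples
#' relaxation_survival(c(0, 1, 12), mse_params(2, 1, 0.1))
#' @export
relaxation_survival <- function(t, params) {
  params <- as_mse_params(params)
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  exp(-(t / params$tau0) * (1 + t / params$tau1)^(params$beta - 1))
}

#' MSE heat-flow model
#'
#' Evaluates the mass-normalised exothermic power of a relaxing glass,
#' `P(t) = 277.8 * (dHr_inf/tau0) * (1 + beta*t/tau1) *
#' (1 + t/tau1)^(beta-2) * Phi(t)` in microwatts per gram, with time in
#' hours. This is exactly `-277.8 * dHr_inf * dPhi/dt`, so the integral of
#' `P` over all time returns the full amplitude `dHr_inf`.
#'
#' @param t Time in hours, `>= 0`; vectorised.
#' @param params An [mse_params] object.
#' @param ctx A [thermal_context], or a single non-negative number taken
#'   directly as `dHr_inf` in J/g.
#'
#' @return Power in uW/g, non-negative, strictly decreasing in `t`.
#' @examples
#' mse_power(0, mse_params(1, 0.5, 0.5), ctx = 1)  # 277.8 uW/g
#' @export
mse_power <- function(t, params, ctx) {
  params <- as_mse_params(params)
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  h <- if (inherits(ctx, "thermal_context")) ctx$delta_h_r_inf else as.numeric(ctx)
  stopifnot(length(h) == 1L, is.finite(h))
  if (h < 0) stop("delta_h_r_inf must be non-negative")
  u <- t / params$tau1
  mse_power_constant * (h / params$tau0) * (1 + params$beta * u) *
    (1 + u)^(params$beta - 2) *
    exp(-(t / params$tau0) * (1 + u)^(params$beta - 1))
}

#' Composite relaxation time tau-beta
#'
#' Summarises a fitted MSE parameter triple as a single relaxation time in
#' hours. The default `"kww"` convention is the long-time
#' Kohlrausch-equivalent composite `tau_beta = tau0 * tau1^(beta - 1)`,
#' i.e. the `tau^beta` that the MSE exponent converges to for `t >> tau1`;
#' it is robust to the strong correlation between tau0 and beta in fits.
#' The alternative `"tau0_beta"` convention returns `tau0^beta`.
#'
#' @param params An [mse_params] object.
#' @param convention `"kww"` (default) or `"tau0_beta"`.
#'
#' @return Relaxation time in hours (positive). Under either convention the
#'   value reduces to `tau0` when `tau1 = 1` h ("kww") or `beta = 1` (both).
#' @examples
#' tau_beta(mse_params(2, 0.5, 0.5))  # 2 * 0.5^(-0.5) = 2.8284 h
#' @export
tau_beta <- function(params, convention = c("kww", "tau0_beta")) {
  params <- as_mse_params(params)
  convention <- match.arg(convention)
  switch(convention,
         kww = params$tau0 * params$tau1^(params$beta - 1),
         tau0_beta = params$tau0^params$beta)
}

# coerce list-like input (e.g. from serialisation) through validation
as_mse_params <- function(x) {
  if (inherits(x, "mse_params")) return(x)
  if (is.list(x) && all(c("tau0", "tau1", "beta") %in% names(x)))
    return(mse_params(x$tau0, x$tau1, x$beta))
  stop("not an mse_params object")
}
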