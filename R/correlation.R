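# Relaxation-crystallization correlation and prediction.
#
# Crystallization time (hours) is regressed on the relaxation time
# tau_beta (hours) across freeze-drying processes of ONE formulation at
# ONE storage temperature: only different processes of the same formulation
# are comparable, so pooling across formulations or temperatures is an
# error, not a warning.

#' Linear correlation of relaxation time with crystallization time
#'
#' Ordinary least squares of `cryst_time ~ tau_beta`, with r-squared,
#' Kendall rank agreement (tau-b) and the residual standard deviation. The
#' slope has the units "hours of crystallization time per hour of
#' relaxation time"; a slope of 600 means a 1 h longer relaxation time buys
#' roughly 25 days of crystallization delay.
#'
#' @param tau_beta_h Relaxation times in hours (one per process).
#' @param cryst_time_h Crystallization times in hours, same length.
#' @param formulation,temperature Optional scope labels; if vectors are
#'   supplied they must be constant, otherwise an error is raised (pairs
#'   from different formulations or temperatures must not be pooled).
#'
#' @return An object of class `relaxation_correlation` with fields `slope`,
#'   `intercept`, `r2`, `kendall_tau`, `residual_sd`, `n`, `fit` (the
#'   underlying `lm`), `range_tau_beta`, `formulation`, `temperature`.
#'   Warns when `n < 4` (a line through three points is not statistically
#'   robust).
#' @export
linear_correlation <- function(tau_beta_h, cryst_time_h,
                               formulation = NULL, temperature = NULL) {
  stopifnot(is.numeric(tau_beta_h), is.numeric(cryst_time_h),
            length(tau_beta_h) == length(cryst_time_h))
  if (!is.null(formulation) && length(unique(formulation)) > 1L)
    stop("cannot pool pairs across formulations: only different processes ",
         "of the same formulation can be compared")
  if (!is.null(temperature) && length(unique(temperature)) > 1L)
    stop("cannot pool pairs across storage temperatures")
  if (anyNA(tau_beta_h) || anyNA(cryst_time_h))
    stop("missing values in correlation input")
  n <- length(tau_beta_h)
  if (n < 2L) stop("need at least two (tau_beta, crystallization time) pairs")
  if (stats::sd(tau_beta_h) == 0)
    stop("degenerate predictor: all tau_beta values equal")
  if (n < 4L)
    warning("only ", n, " pairs: a linear correlation with so few points ",
            "is statistically not robust")
  df <- data.frame(tau_beta_h = tau_beta_h, cryst_time_h = cryst_time_h)
  fit <- stats::lm(cryst_time_h ~ tau_beta_h, data = df)
  tss <- sum((cryst_time_h - mean(cryst_time_h))^2)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = r2,
    kendall_tau = if (stats::sd(cryst_time_h) == 0) NA_real_ else
      rank_agreement(tau_beta_h, cryst_time_h),
    residual_sd = if (n > 2L) sqrt(rss / (n - 2L)) else NA_real_,
    n = n, fit = fit,
    range_tau_beta = range(tau_beta_h),
    formulation = if (is.null(formulation)) NA_character_ else formulation[1L],
    temperature = if (is.null(temperature)) NA_real_ else temperature[1L]),
    class = "relaxation_correlation")
}

#' @export
print.relaxation_correlation <- function(x, ...) {
  cat("Relaxation-crystallization correlation")
  if (!is.na(x$formulation)) cat(sprintf(" [%s", x$formulation))
  if (!is.na(x$temperature)) cat(sprintf(" @ %g degC", x$temperature))
  if (!is.na(x$formulation)) cat("]")
  cat("\n")
  cat(sprintf("  cryst_time = %.6g + %.6g * tau_beta  (hours)\n",
              x$intercept, x$slope))
  cat(sprintf("  n = %d, r2 = %.4f, Kendall tau = %.3f, residual sd = %.4g h\n",
              x$n, x$r2, x$kendall_tau, x$residual_sd))
  invisible(x)
}

#' Kendall rank agreement between relaxation and crystallization order
#'
#' Kendall's tau-b between the tau_beta ranks and the crystallization-time
#' ranks; +1 means the relaxation measurement predicts the crystallization
#' order perfectly.
#'
#' @param tau_beta_h,cryst_time_h Paired numeric vectors, no missing
#'   values.
#' @return Kendall tau-b in \[-1, 1\]. All-tied input is an error.
#' @export
rank_agreement <- function(tau_beta_h, cryst_time_h) {
  stopifnot(length(tau_beta_h) == length(cryst_time_h),
            length(tau_beta_h) >= 2L)
  if (anyNA(tau_beta_h) || anyNA(cryst_time_h))
    stop("missing values in rank_agreement input")
  if (stats::sd(tau_beta_h) == 0 || stats::sd(cryst_time_h) == 0)
    stop("all-tied input: rank agreement undefined")
  tau <- stats::cor(tau_beta_h, cryst_time_h, method = "kendall")
  # tau-b is a ratio of integer pair counts; remove normalisation round-off
  if (abs(abs(tau) - 1) < 1e-12) tau <- sign(tau)
  tau
}

#' Predict a crystallization time from a relaxation time
#'
#' Point prediction `intercept + slope * tau_beta` with a new-observation
#' prediction interval from the OLS fit (t-quantile times the standard
#' error for a new response). Predictions outside twice the fitted
#' tau_beta range (the fitted interval extended by half its width on each
#' side) are flagged as extrapolation.
#'
#' @param object A `relaxation_correlation` model.
#' @param tau_beta_h Relaxation time(s) in hours.
#' @param level Prediction-interval coverage (default 0.95).
#' @param ... Unused.
#'
#' @return A `data.frame` with columns `tau_beta_h`, `cryst_time_h`,
#'   `lower_h`, `upper_h`, `extrapolated`.
#' @export
predict.relaxation_correlation <- function(object, tau_beta_h,
                                           level = 0.95, ...) {
  stopifnot(is.numeric(tau_beta_h))
  nd <- data.frame(tau_beta_h = tau_beta_h)
  pr <- suppressWarnings(
    stats::predict(object$fit, newdata = nd, interval = "prediction",
                   level = level))
  rng <- object$range_tau_beta
  w <- diff(rng)
  extrap <- tau_beta_h < rng[1L] - w / 2 | tau_beta_h > rng[2L] + w / 2
  data.frame(tau_beta_h = tau_beta_h,
             cryst_time_h = pr[, "fit"],
             lower_h = pr[, "lwr"], upper_h = pr[, "upr"],
             extrapolated = extrap)
}
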