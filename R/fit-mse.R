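# Constrained MSE fitting of IMC relaxation records.
#
# The constraints tau0 > tau1 > 0 and 0 < beta <= 1 are enforced by
# reparameterisation, never checked post hoc:
#   tau1 = exp(u1), tau0 = tau1 + exp(u2), beta = plogis(u3),
# so every point the optimiser can visit is feasible. Levenberg-Marquardt
# least squares on the unconstrained scale via minpack.lm::nls.lm.

.mse_pack <- function(params) {
  # a start pinned to the beta boundary has a vanishing logit gradient;
  # nudge it inside so the optimiser can move
  beta <- min(max(params$beta, 1e-6), 0.995)
  c(log(params$tau1), log(params$tau0 - params$tau1), stats::qlogis(beta))
}

.mse_unpack <- function(u) {
  tau1 <- exp(u[1L])
  # keep the iterate strictly feasible even when the optimiser drives the
  # gap or the logit to the edge of double precision
  delta <- max(exp(u[2L]), tau1 * 1e-9)
  beta <- min(max(stats::plogis(u[3L]), 1e-12), 1)
  mse_params(tau0 = tau1 + delta, tau1 = tau1, beta = beta)
}

#' Fit the MSE relaxation model to an IMC record
#'
#' Constrained nonlinear least squares of the MSE heat-flow model against a
#' (preprocessed) power-time record. The amplitude `dHr_inf` is fixed from
#' the DSC-derived thermal context by default -- it is a known multiplier,
#' not a free parameter; set `free_amplitude = TRUE` for sensitivity
#' analysis. The constraints `tau0 > tau1` and `0 < beta <= 1` hold at
#' every iterate by construction.
#'
#' @param series A [power_time_series], already trimmed with
#'   [preprocess_imc] if desired.
#' @param ctx A [thermal_context] (supplies the fixed `dHr_inf`).
#' @param start Starting [mse_params]; defaults to the conventional
#'   `tau0 = 2` h, `tau1 = 1` h, `beta = 0.1`.
#' @param free_amplitude If `TRUE`, a multiplicative amplitude factor is
#'   fitted alongside the shape parameters (default `FALSE`).
#' @param tau_beta_convention Passed to [tau_beta].
#' @param control `minpack.lm::nls.lm.control` list; defaults to
#'   `ftol = ptol = 1e-10`, `maxfev = 5000`.
#'
#' @return An object of class `mse_fit`: fields `params` ([mse_params]),
#'   `ctx`, `tau_beta` (h), `tau_beta_convention`, `amplitude` (multiplier
#'   of `dHr_inf`, 1 unless `free_amplitude`), `rss`, `r2_fit`, `n_points`,
#'   `converged`, `start`, `message`. A record with no relaxation signal
#'   (constant power) yields `converged = FALSE` with `NA` parameters
#'   rather than an error.
#' @examples
#' ctx <- thermal_context(25, 60.21, 0.5)
#' tr <- mse_params(2, 1, 0.1)
#' ts <- imc_sampling_grid(12)
#' rec <- power_time_series(ts, mse_power(ts, tr, ctx))
#' fit <- fit_mse(rec, ctx)
#' fit$tau_beta
#' @export
fit_mse <- function(series, ctx, start = mse_params(2, 1, 0.1),
                    free_amplitude = FALSE,
                    tau_beta_convention = c("kww", "tau0_beta"),
                    control = minpack.lm::nls.lm.control(ftol = 1e-10,
                                                        ptol = 1e-10,
                                                        maxfev = 5000,
                                                        maxiter = 1000)) {
  stopifnot(inherits(series, "power_time_series"),
            inherits(ctx, "thermal_context"))
  tau_beta_convention <- match.arg(tau_beta_convention)
  start <- as_mse_params(start)
  n_par <- 3L + as.integer(free_amplitude)
  t <- series$times_h
  p_obs <- series$power_uW_g
  if (length(t) < 10L)
    stop("too few points for fitting (need >= 10, got ", length(t), ")")
  if (length(t) <= n_par) stop("fewer points than parameters")

  no_signal <- stats::sd(p_obs) < .Machine$double.eps^0.5
  make_fit <- function(params, amplitude, converged, msg) {
    p_hat <- if (is.null(params)) rep(NA_real_, length(t)) else
      amplitude * mse_power(t, params, ctx)
    rss <- sum((p_obs - p_hat)^2)
    tss <- sum((p_obs - mean(p_obs))^2)
    structure(list(
      params = params, ctx = ctx,
      tau_beta = if (is.null(params)) NA_real_ else
        tau_beta(params, tau_beta_convention),
      tau_beta_convention = tau_beta_convention,
      amplitude = amplitude,
      rss = rss,
      r2_fit = if (tss > 0) 1 - rss / tss else NA_real_,
      n_points = length(t), converged = converged,
      start = start, free_amplitude = free_amplitude,
      sample_id = series$sample_id, process = series$process,
      formulation = series$formulation, temperature = series$temperature,
      message = msg), class = "mse_fit")
  }

  if (no_signal)
    return(make_fit(NULL, NA_real_, FALSE, "no relaxation signal (constant power)"))

  resid_fn <- function(u) {
    pp <- .mse_unpack(u[1:3])
    amp <- if (free_amplitude) exp(u[4L]) else 1
    amp * mse_power(t, pp, ctx) - p_obs
  }
  u0 <- c(.mse_pack(start), if (free_amplitude) 0)
  res <- minpack.lm::nls.lm(par = u0, fn = resid_fn, control = control)
  params <- .mse_unpack(res$par[1:3])
  amplitude <- if (free_amplitude) exp(res$par[4L]) else 1
  converged <- res$info %in% 1:3
  fit <- make_fit(params, amplitude, converged, res$message)
  # a "fit" that explains nothing is reported, but not as converged
  if (converged && !is.na(fit$r2_fit) && fit$r2_fit <= 0) {
    fit$converged <- FALSE
    fit$message <- paste0(fit$message, " [model explains no variance]")
  }
  fit
}

#' @export
print.mse_fit <- function(x, ...) {
  cat("MSE relaxation fit")
  if (!is.na(x$sample_id)) cat(sprintf(" for '%s'", x$sample_id))
  cat("\n")
  if (is.null(x$params)) {
    cat("  not converged:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  tau0 = %.6g h, tau1 = %.6g h, beta = %.6g\n",
              x$params$tau0, x$params$tau1, x$params$beta))
  cat(sprintf("  tau_beta = %.6g h  (%s convention)\n",
              x$tau_beta, x$tau_beta_convention))
  cat(sprintf("  dHr_inf = %.6g J/g (fixed%s), n = %d, rss = %.4g, R2 = %.6g\n",
              x$ctx$delta_h_r_inf,
              if (x$free_amplitude) sprintf(", amplitude %.4g", x$amplitude) else "",
              x$n_points, x$rss, x$r2_fit))
  if (!x$converged) cat("  WARNING: not converged:", x$message, "\n")
  invisible(x)
}

#' One-row tabular summary of an MSE fit
#'
#' Flattens an [fit_mse] result into a single data-frame row suitable for
#' binding across samples and writing to CSV. Non-converged fits keep their
#' metadata but carry `NA` parameter cells.
#'
#' @param fit An `mse_fit`.
#' @return A one-row `data.frame`.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "mse_fit"))
  ok <- !is.null(fit$params)
  data.frame(
    sample_id = fit$sample_id, process = fit$process,
    formulation = fit$formulation, temperature_C = fit$temperature,
    tau0_h = if (ok) fit$params$tau0 else NA_real_,
    tau1_h = if (ok) fit$params$tau1 else NA_real_,
    beta = if (ok) fit$params$beta else NA_real_,
    tau_beta_h = fit$tau_beta,
    tau_beta_convention = fit$tau_beta_convention,
    delta_h_r_inf_J_g = fit$ctx$delta_h_r_inf,
    amplitude = fit$amplitude,
    rss = fit$rss, r2_fit = fit$r2_fit, n_points = fit$n_points,
    converged = fit$converged,
    stringsAsFactors = FALSE)
}
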