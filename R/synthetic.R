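# Synthetic calorimetry data with known ground truth.
#
# The generators emulate the study design the analysis modules were built
# for: five freeze-drying processes (differing only in their freezing
# step) of one formulation, measured by 12 h IMC relaxation records,
# screened for crystallization either by leaving fast crystallizers in the
# calorimeter (exotherm peak) or by weekly DSC of stored aliquots. Every
# generated object carries its ground truth so round-trip recovery can be
# asserted at each pipeline stage.
#
# All randomness flows from one seed: generate_study() seeds once and then
# draws per-record sub-seeds in a fixed order (documented splitting
# scheme), so identical seeds give bit-identical studies.

#' Configuration of a synthetic relaxation-crystallization study
#'
#' Defaults encode the emulated study conditions: five processes with
#' composite relaxation times spanning 1.2-4.8 h (controlled nucleation CN
#' shortest, quench cooling QN longest), a linear crystallization law with
#' slope 601.35 h of crystallization time per hour of relaxation time and
#' a 60 h (2.5 day) vial-to-vial scatter, per-process glass-transition
#' temperatures of a 2 mg/mL protein + 1.6 mg/mL polysorbate sucrose
#' formulation, the 2 s / 10 s / 60 s calorimeter sampling scheme, and
#' weekly DSC storage sampling for 20 weeks.
#'
#' @param processes Process labels.
#' @param formulation Formulation label.
#' @param temperature Storage/measurement temperature, degC.
#' @param true_params Named list of [mse_params], one per process.
#' @param tg,delta_cp Named numeric vectors (degC, J/(g K)) per process.
#' @param cryst_intercept_h,cryst_slope_h_per_h,cryst_sd_h Crystallization
#'   law `t_c = a + b * tau_beta + N(0, sd)`, hours.
#' @param path `"storage"` (weekly DSC of aliquots) or `"imc"` (extended
#'   calorimeter record with exotherm).
#' @param imc_noise_uW_g,imc_drift_uW_g_h IMC white-noise sd and linear
#'   baseline drift.
#' @param exotherm_enthalpy_J_g,exotherm_sigma_rise_h,exotherm_sigma_fall_h
#'   Split-Gaussian IMC exotherm shape.
#' @param double_peak If `TRUE`, pooled-vial records get a second exotherm
#'   offset by 2-5 days.
#' @param dsc_snr,dsc_tg_width_K,dsc_peak_sigma_K,dsc_t_range DSC shape
#'   parameters.
#' @param cryst_onset_C,onset_drift_K_day Above-Tg crystallization peak
#'   onset and its drift during storage.
#' @param frac_scale_days Time scale of the logistic crystallized-fraction
#'   ramp during storage.
#' @param storage_weeks Sampling weeks of the storage trajectory.
#' @param moisture_factor Residual-moisture covariate: a multiplicative
#'   factor applied to every process's `tau0` (with `tau1` fixed at 1 h
#'   this scales tau_beta proportionally, and the crystallization law
#'   propagates the shift to the crystallization times -- the
#'   plasticization effect acts proportionally on both). Default 1.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(
    processes = c("CN", "AN1.5", "AN3.0", "RN", "QN"),
    formulation = "2mgmL_1.6PS_Suc",
    temperature = 25,
    true_params = list(
      "CN" = mse_params(1.2, 1, 0.1),
      "AN1.5" = mse_params(2.2, 1, 0.1),
      "AN3.0" = mse_params(2.8, 1, 0.1),
      "RN" = mse_params(3.5, 1, 0.1),
      "QN" = mse_params(4.8, 1, 0.1)),
    tg = c("CN" = 48.29, "AN1.5" = 60.19, "AN3.0" = 60.01,
           "RN" = 62.27, "QN" = 64.05),
    delta_cp = stats::setNames(rep(0.5, length(processes)), processes),
    cryst_intercept_h = 24,
    cryst_slope_h_per_h = 601.35,
    cryst_sd_h = 60,
    path = c("storage", "imc"),
    imc_noise_uW_g = 0.2,
    imc_drift_uW_g_h = 0.01,
    exotherm_enthalpy_J_g = 45,
    exotherm_sigma_rise_h = 6,
    exotherm_sigma_fall_h = 12,
    double_peak = FALSE,
    dsc_snr = 50,
    dsc_tg_width_K = 3,
    dsc_peak_sigma_K = 2,
    dsc_t_range = c(25, 160),
    cryst_onset_C = 85,
    onset_drift_K_day = -0.05,
    frac_scale_days = 3.5,
    storage_weeks = 0:20,
    moisture_factor = 1) {
  path <- match.arg(path)
  stopifnot(length(processes) >= 1L,
            all(processes %in% names(true_params)),
            all(processes %in% names(tg)),
            all(processes %in% names(delta_cp)),
            cryst_sd_h >= 0, imc_noise_uW_g >= 0, dsc_snr > 0,
            moisture_factor > 0)
  for (p in processes) {
    pp <- as_mse_params(true_params[[p]])
    if (moisture_factor != 1)
      pp <- mse_params(pp$tau0 * moisture_factor, pp$tau1, pp$beta)
    true_params[[p]] <- pp
  }
  tb <- vapply(true_params[processes], tau_beta, numeric(1))
  structure(list(processes = processes, formulation = formulation,
                 temperature = temperature,
                 true_params = true_params, tg = tg, delta_cp = delta_cp,
                 tau_beta_true = tb,
                 cryst_intercept_h = cryst_intercept_h,
                 cryst_slope_h_per_h = cryst_slope_h_per_h,
                 cryst_sd_h = cryst_sd_h, path = path,
                 imc_noise_uW_g = imc_noise_uW_g,
                 imc_drift_uW_g_h = imc_drift_uW_g_h,
                 exotherm_enthalpy_J_g = exotherm_enthalpy_J_g,
                 exotherm_sigma_rise_h = exotherm_sigma_rise_h,
                 exotherm_sigma_fall_h = exotherm_sigma_fall_h,
                 double_peak = double_peak,
                 dsc_snr = dsc_snr, dsc_tg_width_K = dsc_tg_width_K,
                 dsc_peak_sigma_K = dsc_peak_sigma_K,
                 dsc_t_range = dsc_t_range,
                 cryst_onset_C = cryst_onset_C,
                 onset_drift_K_day = onset_drift_K_day,
                 frac_scale_days = frac_scale_days,
                 storage_weeks = storage_weeks,
                 moisture_factor = moisture_factor),
            class = "study_config")
}

#' Pre-test study configuration (placebo, fast crystallization)
#'
#' A four-process variant emulating a placebo pre-test in which all
#' samples crystallize inside the calorimeter within days: shallower
#' crystallization law (intercept 24 h, slope 60 h/h), small vial scatter
#' (12 h -- fast crystallization leaves little room for vial-to-vial
#' spread), narrower exotherms, IMC fast path.
#'
#' @param ... Overrides passed to [study_config].
#' @export
study_config_pretest <- function(...) {
  defaults <- list(
    processes = c("CN", "AN1.5", "RN", "QN"),
    formulation = "1.6PS_Suc_placebo",
    temperature = 40,
    true_params = list(
      "CN" = mse_params(1.2, 1, 0.1),
      "AN1.5" = mse_params(2.2, 1, 0.1),
      "RN" = mse_params(3.5, 1, 0.1),
      "QN" = mse_params(4.8, 1, 0.1)),
    tg = c("CN" = 48.98, "AN1.5" = 60.09, "RN" = 60.21, "QN" = 72.03),
    delta_cp = c("CN" = 0.5, "AN1.5" = 0.5, "RN" = 0.5, "QN" = 0.5),
    cryst_slope_h_per_h = 60, cryst_sd_h = 12,
    exotherm_sigma_rise_h = 3, exotherm_sigma_fall_h = 6,
    path = "imc")
  args <- utils::modifyList(defaults, list(...))
  do.call(study_config, args)
}

#' Generate one synthetic IMC power-time record
#'
#' Evaluates the MSE heat-flow model at the true parameters on the
#' standard sampling grid and superimposes optional crystallization
#' exotherms (split Gaussians; pooled-vial double peaks are two of them),
#' a linear baseline drift, an optional early exothermic transient with
#' endothermic valley (the controlled-nucleation anomaly, for fitter
#' robustness testing), and white noise.
#'
#' @param params True [mse_params].
#' @param delta_h_r_inf_J_g True relaxation amplitude, J/g.
#' @param duration_h Record length, hours.
#' @param noise_sd_uW_g White-noise standard deviation, uW/g.
#' @param drift_uW_g_h Linear drift slope, uW/g per hour.
#' @param exotherms `NULL` or a `data.frame` with columns `time_h`,
#'   `enthalpy_J_g`, `sigma_rise_h`, `sigma_fall_h`.
#' @param early_transient If `TRUE`, add an exothermic bump at 0.58 h and
#'   a shallow endothermic valley.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param ... Metadata passed to [power_time_series].
#'
#' @return A [power_time_series] with attribute `ground_truth` (list with
#'   the generating parameters, `tau_beta_true`, exotherm table and noise
#'   settings).
#' @export
generate_imc_curve <- function(params, delta_h_r_inf_J_g, duration_h = 12,
                               noise_sd_uW_g = 0.2, drift_uW_g_h = 0.01,
                               exotherms = NULL, early_transient = FALSE,
                               seed = NULL, ...) {
  params <- as_mse_params(params)
  if (!is.null(seed)) set.seed(seed)
  t <- imc_sampling_grid(duration_h)
  p <- mse_power(t, params, delta_h_r_inf_J_g) + drift_uW_g_h * t
  if (!is.null(exotherms) && nrow(exotherms) > 0L) {
    if (any(exotherms$time_h > duration_h))
      stop("exotherm at ", max(exotherms$time_h),
           " h lies beyond the record duration of ", duration_h, " h")
    for (k in seq_len(nrow(exotherms))) {
      sl <- exotherms$sigma_rise_h[k]; sr <- exotherms$sigma_fall_h[k]
      h <- exotherms$enthalpy_J_g[k] / 3.6e-3 / (sqrt(pi / 2) * (sl + sr))
      s <- ifelse(t < exotherms$time_h[k], sl, sr)
      p <- p + h * exp(-(t - exotherms$time_h[k])^2 / (2 * s^2))
    }
  }
  if (early_transient) {
    p <- p + 0.3 * delta_h_r_inf_J_g * exp(-(t - 0.58)^2 / (2 * 0.15^2)) -
      0.05 * delta_h_r_inf_J_g * exp(-(t - 36)^2 / (2 * 24^2))
  }
  if (noise_sd_uW_g > 0) p <- p + stats::rnorm(length(t), 0, noise_sd_uW_g)
  out <- power_time_series(t, p, ...)
  attr(out, "ground_truth") <- list(
    params = params, tau_beta_true = tau_beta(params),
    delta_h_r_inf_J_g = delta_h_r_inf_J_g, exotherms = exotherms,
    noise_sd_uW_g = noise_sd_uW_g, drift_uW_g_h = drift_uW_g_h,
    early_transient = early_transient)
  out
}

#' Generate one synthetic DSC thermogram
#'
#' Reversing curve: linear instrument baseline plus the endothermic
#' heat-capacity step (logistic sigmoid of 10-90% width `tg_width_K`) at
#' Tg. Total curve: the same plus a Gaussian crystallization exotherm
#' above Tg whose enthalpy scales with the remaining amorphous fraction
#' `1 - crystallized_fraction`. The configured `cryst_onset_C` is the
#' tangent-method onset, i.e. the peak centre sits at
#' `cryst_onset_C + 2 * peak_sigma_K`. Noise is white with sd equal to the
#' cp-step height divided by `snr`.
#'
#' @param tg Glass-transition midpoint, degC; must lie inside `t_range`
#'   with room for baselines.
#' @param delta_cp Heat-capacity step, J/(g K).
#' @param cryst_onset_C Tangent onset of the exotherm, degC.
#' @param cryst_enthalpy_J_g Full (fresh-sample) crystallization enthalpy.
#' @param crystallized_fraction Fraction already crystallized, in \[0, 1\].
#' @param heating_rate K/min.
#' @param t_range Scan range, degC.
#' @param snr Signal-to-noise ratio of the cp step.
#' @param tg_width_K 10-90% width of the transition, K.
#' @param peak_sigma_K Gaussian sd of the exotherm, K.
#' @param baseline_W_g,baseline_slope_W_gK Linear instrument baseline.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#'
#' @return A [dsc_thermogram] with attribute `ground_truth`.
#' @export
generate_dsc_thermogram <- function(tg, delta_cp = 0.5, cryst_onset_C = 85,
                                    cryst_enthalpy_J_g = 45,
                                    crystallized_fraction = 0,
                                    heating_rate = 2, t_range = c(25, 160),
                                    snr = 50, tg_width_K = 3,
                                    peak_sigma_K = 2,
                                    baseline_W_g = 0.002,
                                    baseline_slope_W_gK = -2e-6,
                                    seed = NULL) {
  stopifnot(crystallized_fraction >= 0, crystallized_fraction <= 1,
            delta_cp > 0, snr > 0)
  if (tg <= t_range[1L] + 23 || tg >= t_range[2L] - 23)
    stop("Tg of ", tg, " degC too close to the scan limits [",
         t_range[1L], ", ", t_range[2L], "] for baseline fitting")
  if (!is.null(seed)) set.seed(seed)
  rate_Ks <- heating_rate / 60
  tt <- seq(t_range[1L], t_range[2L], by = rate_Ks)  # 1 Hz sampling
  s <- tg_width_K / 4.394                            # logistic 10-90% width
  step <- delta_cp * rate_Ks
  base <- baseline_W_g + baseline_slope_W_gK * (tt - t_range[1L])
  rev_clean <- base - step * stats::plogis((tt - tg) / s)
  e_eff <- cryst_enthalpy_J_g * (1 - crystallized_fraction)
  mu <- cryst_onset_C + 2 * peak_sigma_K
  peak <- if (e_eff > 0)
    e_eff * rate_Ks / (peak_sigma_K * sqrt(2 * pi)) *
      exp(-(tt - mu)^2 / (2 * peak_sigma_K^2)) else 0
  noise <- step / snr
  out <- dsc_thermogram(
    tt,
    rev_clean + stats::rnorm(length(tt), 0, noise),
    rev_clean + peak + stats::rnorm(length(tt), 0, noise),
    heating_rate = heating_rate)
  attr(out, "ground_truth") <- list(
    tg = tg, delta_cp = delta_cp, cryst_onset_C = cryst_onset_C,
    cryst_peak_T = mu,
    cryst_enthalpy_J_g = e_eff, crystallized_fraction = crystallized_fraction,
    snr = snr, noise_sd_W_g = noise)
  out
}

#' Generate a weekly storage trajectory of DSC thermograms
#'
#' The crystallized fraction during storage follows a logistic ramp
#' centred at the true crystallization time `t_c_days` with time scale
#' `frac_scale_days` (so the above-Tg enthalpy crosses half its initial
#' value exactly at `t_c_days`), and the exotherm onset drifts linearly
#' with storage age.
#'
#' @param tg,delta_cp,cryst_onset_C,cryst_enthalpy_J_g,seed,... As in
#'   [generate_dsc_thermogram].
#' @param t_c_days True storage crystallization time, days.
#' @param times_days Sampling times, days (default weekly for 20 weeks).
#' @param frac_scale_days Logistic time scale, days.
#' @param onset_drift_K_day Onset drift, K per day.
#'
#' @return A list with `times_days`, `thermograms` (list of
#'   [dsc_thermogram]) and `ground_truth`.
#' @export
generate_storage_trajectory <- function(tg, delta_cp = 0.5,
                                        cryst_onset_C = 85,
                                        cryst_enthalpy_J_g = 45,
                                        t_c_days,
                                        times_days = 7 * (0:20),
                                        frac_scale_days = 3.5,
                                        onset_drift_K_day = -0.05,
                                        seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tgs <- lapply(times_days, function(td) {
    frac <- stats::plogis((td - t_c_days) / frac_scale_days)
    generate_dsc_thermogram(
      tg = tg, delta_cp = delta_cp,
      cryst_onset_C = cryst_onset_C + onset_drift_K_day * td,
      cryst_enthalpy_J_g = cryst_enthalpy_J_g,
      crystallized_fraction = frac, seed = NULL, ...)
  })
  list(times_days = times_days, thermograms = tgs,
       ground_truth = list(tg = tg, delta_cp = delta_cp,
                           t_c_days = t_c_days,
                           frac_scale_days = frac_scale_days,
                           cryst_onset_C = cryst_onset_C,
                           onset_drift_K_day = onset_drift_K_day,
                           cryst_enthalpy_J_g = cryst_enthalpy_J_g))
}

#' Generate a full multi-process synthetic study
#'
#' For each process: a relaxation IMC record (12 h; extended past the
#' exotherm on the fast path), a week-0 DSC thermogram, and -- on the
#' storage path -- a weekly thermogram trajectory. True crystallization
#' times are drawn from the linear law
#' `t_c = a + b * tau_beta_true + N(0, sd)` (clamped to at least 36 h so
#' the exotherm stays clear of the relaxation fit window). A truth table
#' accompanies the data.
#'
#' @param config A [study_config].
#' @param seed Integer master seed. All per-record sub-seeds are drawn
#'   from it in a fixed order.
#'
#' @return A list of class `synthetic_study`: `config`, `truth` (a
#'   `data.frame`), `imc` (named list of [power_time_series]), `dsc_week0`
#'   (named list of [dsc_thermogram]) and, on the storage path,
#'   `trajectories` (named list from [generate_storage_trajectory]).
#' @export
generate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  np <- length(config$processes)
  # fixed splitting scheme: one noise draw + three sub-seeds per process
  eps <- stats::rnorm(np, 0, config$cryst_sd_h)
  sub <- matrix(sample.int(.Machine$integer.max - 1L, 3L * np),
                nrow = np, ncol = 3L)
  tb <- config$tau_beta_true
  t_c_h <- pmax(config$cryst_intercept_h +
                  config$cryst_slope_h_per_h * tb + eps, 36)
  imc <- list(); dsc0 <- list(); traj <- list()
  for (i in seq_len(np)) {
    p <- config$processes[i]
    pars <- config$true_params[[p]]
    dhr <- delta_h_r_inf(config$temperature, config$tg[[p]],
                         config$delta_cp[[p]])
    if (config$path == "imc") {
      ex <- data.frame(time_h = t_c_h[i],
                       enthalpy_J_g = config$exotherm_enthalpy_J_g,
                       sigma_rise_h = config$exotherm_sigma_rise_h,
                       sigma_fall_h = config$exotherm_sigma_fall_h)
      if (config$double_peak) {
        set.seed(sub[i, 3L])
        off <- stats::runif(1, 48, 120)  # 2-5 days between pooled vials
        ex <- rbind(ex, within(ex[1L, ], {
          time_h <- time_h + off
          enthalpy_J_g <- enthalpy_J_g * 0.8
        }))
      }
      dur <- max(ex$time_h) + 4 * config$exotherm_sigma_fall_h + 12
      imc[[p]] <- generate_imc_curve(
        pars, dhr, duration_h = dur,
        noise_sd_uW_g = config$imc_noise_uW_g,
        drift_uW_g_h = config$imc_drift_uW_g_h,
        exotherms = ex, seed = sub[i, 1L],
        sample_id = p, process = p, formulation = config$formulation,
        temperature = config$temperature)
    } else {
      imc[[p]] <- generate_imc_curve(
        pars, dhr, duration_h = 12,
        noise_sd_uW_g = config$imc_noise_uW_g,
        drift_uW_g_h = config$imc_drift_uW_g_h,
        seed = sub[i, 1L],
        sample_id = p, process = p, formulation = config$formulation,
        temperature = config$temperature)
      traj[[p]] <- generate_storage_trajectory(
        tg = config$tg[[p]], delta_cp = config$delta_cp[[p]],
        cryst_onset_C = config$cryst_onset_C,
        cryst_enthalpy_J_g = config$exotherm_enthalpy_J_g,
        t_c_days = t_c_h[i] / 24,
        times_days = 7 * config$storage_weeks,
        frac_scale_days = config$frac_scale_days,
        onset_drift_K_day = config$onset_drift_K_day,
        snr = config$dsc_snr, tg_width_K = config$dsc_tg_width_K,
        peak_sigma_K = config$dsc_peak_sigma_K,
        t_range = config$dsc_t_range, seed = sub[i, 2L])
    }
    dsc0[[p]] <- generate_dsc_thermogram(
      tg = config$tg[[p]], delta_cp = config$delta_cp[[p]],
      cryst_onset_C = config$cryst_onset_C,
      cryst_enthalpy_J_g = config$exotherm_enthalpy_J_g,
      crystallized_fraction = 0,
      snr = config$dsc_snr, tg_width_K = config$dsc_tg_width_K,
      peak_sigma_K = config$dsc_peak_sigma_K,
      t_range = config$dsc_t_range,
      seed = if (config$path == "imc") sub[i, 2L] else sub[i, 3L])
  }
  truth <- data.frame(
    process = config$processes,
    tau0_h = vapply(config$true_params[config$processes],
                    function(x) x$tau0, numeric(1)),
    tau1_h = vapply(config$true_params[config$processes],
                    function(x) x$tau1, numeric(1)),
    beta = vapply(config$true_params[config$processes],
                  function(x) x$beta, numeric(1)),
    tau_beta_true_h = as.numeric(tb),
    tg_C = as.numeric(config$tg[config$processes]),
    delta_cp_J_gK = as.numeric(config$delta_cp[config$processes]),
    cryst_time_true_h = as.numeric(t_c_h),
    path = config$path, seed = seed,
    stringsAsFactors = FALSE)
  structure(list(config = config, seed = seed, truth = truth, imc = imc,
                 dsc_week0 = dsc0,
                 trajectories = if (config$path == "storage") traj else NULL),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d processes of '%s' at %g degC (%s path, seed %d)\n",
              length(x$config$processes), x$config$formulation,
              x$config$temperature, x$config$path, x$seed))
  print(x$truth[, c("process", "tau_beta_true_h", "cryst_time_true_h")],
        row.names = FALSE)
  invisible(x)
}
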