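# End-to-end orchestration: relaxation fits -> crystallization times ->
# correlation, with per-sample error isolation and provenance echoing.

#' Run the full relaxation-crystallization pipeline on a study
#'
#' For every process: extract Tg and delta_cp from the week-0 DSC
#' thermogram, build the thermal context at the study temperature, fit the
#' MSE model to the (trimmed) 12 h relaxation record, and determine the
#' crystallization time -- from the exotherm maximum of the extended IMC
#' record (fast path) or from the weekly DSC trajectory (slow path). The
#' per-process results are then correlated within the study's single
#' (formulation, temperature) scope.
#'
#' Failures of individual samples are collected and reported; the
#' remaining samples are still processed and correlated.
#'
#' @param study A `synthetic_study` from [generate_study], or any list
#'   with the same fields (`config`, `imc`, `dsc_week0`, `trajectories`).
#' @param trim_start Hours trimmed from the start of the relaxation
#'   record (default 0, the nominal procedure).
#' @param fit_duration End of the relaxation fit window, hours.
#' @param theta Enthalpy-fraction threshold of the storage rule.
#' @param peak_policy Double-peak policy for [imc_crystallization_time].
#' @param tau_beta_convention Passed to [fit_mse].
#' @param refine_peaks Passed to [detect_exotherm_peaks].
#'
#' @return A list of class `study_report`: `results` (one row per
#'   process: fit report, tau_beta, crystallization time in hours),
#'   `model` (a `relaxation_correlation`, or `NULL` if fewer than two
#'   samples survived), `errors` (named list of failure messages),
#'   `options` (the effective configuration echoed for provenance).
#' @export
run_pipeline <- function(study, trim_start = 0, fit_duration = 12,
                         theta = 0.5, peak_policy = "first",
                         tau_beta_convention = "kww", refine_peaks = TRUE) {
  stopifnot(!is.null(study$config), !is.null(study$imc),
            !is.null(study$dsc_week0))
  cfg <- study$config
  errors <- list()
  rows <- list()
  for (p in names(study$imc)) {
    row <- tryCatch({
      feats <- dsc_features(study$dsc_week0[[p]])
      ctx <- thermal_context(cfg$temperature, feats$tg_midpoint,
                             feats$delta_cp)
      rec <- preprocess_imc(study$imc[[p]], trim_start, fit_duration)
      fit <- fit_mse(rec, ctx, tau_beta_convention = tau_beta_convention)
      cr_h <- if (cfg$path == "imc") {
        peaks <- detect_exotherm_peaks(study$imc[[p]],
                                       fit_window_h = fit_duration,
                                       refine = refine_peaks)
        as.numeric(imc_crystallization_time(peaks, policy = peak_policy))
      } else {
        tr <- study$trajectories[[p]]
        wk <- weekly_features(tr$thermograms, tr$times_days)
        rec_s <- storage_record(p, cfg$temperature, tr$times_days, wk)
        24 * as.numeric(storage_crystallization_time(rec_s, theta = theta))
      }
      cbind(fit_report(fit), cryst_time_h = cr_h,
            status = if (is.na(cr_h)) "amorphous" else "crystallized")
    }, error = function(e) {
      errors[[p]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(row)) rows[[p]] <- row
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  model <- NULL
  if (!is.null(results)) {
    ok <- results$converged & !is.na(results$cryst_time_h)
    if (sum(ok) >= 2L && stats::sd(results$tau_beta_h[ok]) > 0)
      model <- suppressWarnings(linear_correlation(
        results$tau_beta_h[ok], results$cryst_time_h[ok],
        formulation = cfg$formulation, temperature = cfg$temperature))
  }
  structure(list(
    results = results, model = model, errors = errors,
    options = list(package_version = as.character(
                     utils::packageVersion("relaxcryst")),
                   trim_start = trim_start, fit_duration = fit_duration,
                   theta = theta, peak_policy = peak_policy,
                   tau_beta_convention = tau_beta_convention,
                   refine_peaks = refine_peaks, path = cfg$path,
                   formulation = cfg$formulation,
                   temperature = cfg$temperature,
                   seed = study$seed)),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Relaxation-crystallization study report\n")
  if (!is.null(x$results))
    print(x$results[, c("sample_id", "tau_beta_h", "cryst_time_h",
                        "r2_fit", "converged")], row.names = FALSE)
  if (!is.null(x$model)) print(x$model)
  if (length(x$errors)) {
    cat("Failed samples:\n")
    for (p in names(x$errors)) cat("  ", p, ": ", x$errors[[p]], "\n", sep = "")
  }
  invisible(x)
}

#' Extract weekly DSC features from a thermogram trajectory
#'
#' Runs the crystallization-peak extractor (and optionally the glass
#' transition) on each weekly thermogram and assembles the feature table a
#' [storage_record] consumes.
#'
#' @param thermograms List of [dsc_thermogram].
#' @param times_days Sampling times, days.
#' @param with_tg Also extract Tg per week (slower; default `FALSE`).
#'
#' @return A `data.frame` with columns `time_days`, `cryst_onset_C`,
#'   `cryst_peak_T_C`, `cryst_enthalpy_J_g` (plus `tg_C`, `delta_cp_J_gK`).
#' @export
weekly_features <- function(thermograms, times_days, with_tg = FALSE) {
  stopifnot(length(thermograms) == length(times_days))
  rows <- lapply(seq_along(thermograms), function(i) {
    ce <- extract_crystallization_event(thermograms[[i]])
    out <- data.frame(time_days = times_days[i],
                      cryst_onset_C = ce$cryst_onset,
                      cryst_peak_T_C = ce$cryst_peak_T,
                      cryst_enthalpy_J_g = ce$cryst_enthalpy)
    if (with_tg) {
      gt <- extract_glass_transition(thermograms[[i]])
      out$tg_C <- gt$tg_midpoint
      out$delta_cp_J_gK <- gt$delta_cp
    }
    out
  })
  do.call(rbind, rows)
}

#' Read a weekly storage feature table from CSV
#'
#' Fixed dialect: header `week,time_days,tg_C,cryst_onset_C,
#' cryst_enthalpy_J_per_g` (tg column optional).
#'
#' @param path CSV path.
#' @param sample_id,storage_temperature Metadata for the record.
#' @return A [storage_record].
#' @export
read_weekly_features_csv <- function(path, sample_id = NA_character_,
                                     storage_temperature = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_days", "cryst_enthalpy_J_per_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  feats <- data.frame(cryst_enthalpy_J_g = df$cryst_enthalpy_J_per_g)
  if ("cryst_onset_C" %in% names(df)) feats$cryst_onset_C <- df$cryst_onset_C
  if ("tg_C" %in% names(df)) feats$tg_C <- df$tg_C
  storage_record(sample_id, storage_temperature, df$time_days, feats)
}

#' Write a study report to disk
#'
#' Writes `results.csv` (per-sample table), `model.json` (correlation
#' model) and `config.json` (the effective options, package version and
#' seed -- the provenance echo) into `dir`.
#'
#' @param report A `study_report` from [run_pipeline].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(report$results))
    utils::write.csv(report$results, file.path(dir, "results.csv"),
                     row.names = FALSE)
  if (!is.null(report$model)) {
    m <- report$model
    jsonlite::write_json(
      list(slope_h_per_h = m$slope, intercept_h = m$intercept, r2 = m$r2,
           kendall_tau = m$kendall_tau, residual_sd_h = m$residual_sd,
           n = m$n, formulation = m$formulation,
           temperature_C = m$temperature),
      file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(c(report$options, list(errors = report$errors)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
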