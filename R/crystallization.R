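# Crystallization-time determination.
#
# Fast path: long IMC records are screened for crystallization exotherms
# after subtracting a refitted relaxation baseline; the peak maximum is the
# crystallization time. Slow path: weekly DSC feature trajectories during
# storage are converted to a crystallization time by an
# enthalpy-fraction-crossing rule (the above-Tg crystallization enthalpy
# tracks the remaining amorphous fraction) or an onset-drop rule.

#' Detect crystallization exotherms in a long IMC record
#'
#' The MSE relaxation model (with a free amplitude) is refitted to the
#' early, pre-crystallization segment of the record, the model baseline is
#' subtracted over the whole record, and peaks are detected on the smoothed
#' residual with a noise-scaled prominence threshold (median-absolute-
#' deviation estimate, prominence `>= min_prom_sd` sigma). Detected peak
#' times are then refined by a joint fit of split-Gaussian peak shapes plus
#' a linear baseline, which locates each maximum far below the sampling
#' interval even for asymmetric exotherms.
#'
#' @param series A [power_time_series] spanning at least `min_span_h`.
#' @param fit_window_h Length of the initial segment used for the
#'   relaxation-baseline refit, hours (default 12, the standard relaxation
#'   record length).
#' @param smooth_h Running-mean window for detection, hours (default 0.5).
#' @param min_prom_sd Prominence threshold in noise-sd units (default 5).
#' @param refine If `TRUE` (default) refine peak times/areas by the
#'   split-Gaussian model fit; if `FALSE` report the smoothed-residual
#'   maxima (faster, grid-resolution only).
#' @param min_span_h Minimum record span, hours (default 2).
#'
#' @return An object of class `exotherm_peaks`: a `data.frame` with columns
#'   `time_of_maximum_h`, `height_uW_g`, `prominence_uW_g`, `area_J_g`,
#'   ordered by time; zero rows when no exotherm is found.
#' @export
detect_exotherm_peaks <- function(series, fit_window_h = 12, smooth_h = 0.5,
                                  min_prom_sd = 5, refine = TRUE,
                                  min_span_h = 2) {
  stopifnot(inherits(series, "power_time_series"))
  t <- series$times_h
  p <- series$power_uW_g
  if (t[length(t)] - t[1L] < min_span_h)
    stop("record shorter than the minimum window of ", min_span_h, " h")

  # relaxation + instrument baseline from the early segment: MSE shape with
  # free amplitude (dHr_inf absorbed, so no DSC context is needed) plus a
  # drift line, fitted jointly so slow drift does not bleed into residuals
  pre <- t <= min(fit_window_h, t[1L] + (t[length(t)] - t[1L]) / 3)
  baseline <- rep(stats::median(p[pre]), length(t))
  bl_fit <- tryCatch({
    start <- mse_params(2, 1, 0.1)
    u0 <- c(.mse_pack(start), log(max(p[pre][1L], 1e-6)), 0, 0)
    fn <- function(u) {
      pp <- .mse_unpack(u[1:3])
      exp(u[4L]) * mse_power(t[pre], pp, 1) + u[5L] + u[6L] * t[pre] - p[pre]
    }
    res <- minpack.lm::nls.lm(par = u0, fn = fn,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-10, ptol = 1e-10, maxfev = 5000,
                                maxiter = 1000))
    list(params = .mse_unpack(res$par[1:3]), amp = exp(res$par[4L]),
         c0 = res$par[5L], c1 = res$par[6L])
  }, error = function(e) NULL)
  if (!is.null(bl_fit))
    baseline <- bl_fit$amp * mse_power(t, bl_fit$params, 1) +
      bl_fit$c0 + bl_fit$c1 * t
  resid <- p - baseline

  sigma <- .noise_sd(resid)
  # detect on a uniform grid: the acquisition grid mixes 2 s / 10 s / 60 s
  # intervals, which would make an index-based smoothing window span very
  # different times along the record
  dt_u <- stats::median(diff(t[t >= t[1L] + (t[length(t)] - t[1L]) / 2]))
  tu <- seq(t[1L], t[length(t)], by = dt_u)
  ru <- stats::approx(t, resid, tu)$y
  m <- .running_mean(ru, round(smooth_h / dt_u))
  pk <- .find_peaks(m, min_prom = max(min_prom_sd * sigma,
                                      .Machine$double.eps),
                    min_sep = max(3L, round(2 * smooth_h / dt_u)))
  empty <- data.frame(time_of_maximum_h = numeric(0),
                      height_uW_g = numeric(0),
                      prominence_uW_g = numeric(0), area_J_g = numeric(0))
  class(empty) <- c("exotherm_peaks", "data.frame")
  if (nrow(pk) == 0L) return(empty)

  # per-peak width guess from half-prominence crossings of the smoothed trace
  widths <- vapply(seq_len(nrow(pk)), function(k) {
    i <- pk$index[k]
    half <- m[i] - pk$prominence[k] / 2
    l <- i; while (l > 1L && m[l] > half) l <- l - 1L
    r <- i; while (r < length(m) && m[r] > half) r <- r + 1L
    max(tu[r] - tu[l], 4 * dt_u) / 2.355   # FWHM -> sigma
  }, numeric(1))

  if (refine) {
    lo <- max(t[1L], min(tu[pk$index] - 8 * widths))
    hi <- min(t[length(t)], max(tu[pk$index] + 8 * widths))
    win <- which(t >= lo & t <= hi)
    if (length(win) > 15000L)
      win <- win[seq(1L, length(win), length.out = 15000L)]
    tw <- t[win]; rw <- resid[win]
    K <- nrow(pk)
    model <- function(par) {
      out <- par[1L] + par[2L] * (tw - lo)
      for (k in seq_len(K)) {
        j <- 2L + (k - 1L) * 4L
        h <- exp(par[j + 1L]); c0 <- par[j + 2L]
        sl <- exp(par[j + 3L]); sr <- exp(par[j + 4L])
        s <- ifelse(tw < c0, sl, sr)
        out <- out + h * exp(-(tw - c0)^2 / (2 * s^2))
      }
      out
    }
    par0 <- c(0, 0)
    for (k in seq_len(K))
      par0 <- c(par0, log(pk$prominence[k]), tu[pk$index[k]],
                log(widths[k]), log(widths[k]))
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = function(pp) model(pp) - rw,
                         control = minpack.lm::nls.lm.control(maxfev = 4000,
                                                              maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(res)) {
      out <- do.call(rbind, lapply(seq_len(K), function(k) {
        j <- 2L + (k - 1L) * 4L
        h <- exp(res$par[j + 1L]); c0 <- res$par[j + 2L]
        sl <- exp(res$par[j + 3L]); sr <- exp(res$par[j + 4L])
        data.frame(time_of_maximum_h = c0, height_uW_g = h,
                   prominence_uW_g = pk$prominence[k],
                   area_J_g = h * sqrt(pi / 2) * (sl + sr) * 3.6e-3)
      }))
      # a refinement that wandered away from its detection is rejected
      bad <- abs(out$time_of_maximum_h - tu[pk$index]) > 4 * widths |
        out$time_of_maximum_h < t[1L] | out$time_of_maximum_h > t[length(t)]
      if (any(bad)) {
        out$time_of_maximum_h[bad] <- tu[pk$index][bad]
        out$height_uW_g[bad] <- m[pk$index][bad]
      }
      out <- out[order(out$time_of_maximum_h), ]
      rownames(out) <- NULL
      class(out) <- c("exotherm_peaks", "data.frame")
      return(out)
    }
  }

  # unrefined: grid-resolution maxima with trapezoid areas over +-4 sigma
  areas <- vapply(seq_len(nrow(pk)), function(k) {
    sel <- which(tu >= tu[pk$index[k]] - 4 * widths[k] &
                 tu <= tu[pk$index[k]] + 4 * widths[k])
    sum(diff(tu[sel]) * (m[sel][-1L] + m[sel][-length(sel)]) / 2) * 3.6e-3
  }, numeric(1))
  out <- data.frame(time_of_maximum_h = tu[pk$index], height_uW_g = m[pk$index],
                    prominence_uW_g = pk$prominence, area_J_g = areas)
  out <- out[order(out$time_of_maximum_h), ]
  rownames(out) <- NULL
  class(out) <- c("exotherm_peaks", "data.frame")
  out
}

#' Crystallization time from detected IMC exotherms
#'
#' Applies the peak-maximum convention: the time of the selected exotherm
#' maximum is the crystallization time. Pooled-vial records can show double
#' peaks; the default policy takes the first maximum (the first vial to
#' crystallize), with `"largest_area"` and `"mean_of_maxima"` selectable.
#'
#' @param peaks An `exotherm_peaks` data frame from
#'   [detect_exotherm_peaks].
#' @param policy `"first"` (default), `"largest_area"` or
#'   `"mean_of_maxima"`.
#'
#' @return Crystallization time in hours with attribute `policy`;
#'   `NA_real_` when no peak was detected.
#' @export
imc_crystallization_time <- function(peaks,
                                     policy = c("first", "largest_area",
                                                "mean_of_maxima")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L)
    return(structure(NA_real_, policy = policy))
  val <- switch(policy,
                first = peaks$time_of_maximum_h[1L],
                largest_area = peaks$time_of_maximum_h[
                  which.max(peaks$area_J_g)],
                mean_of_maxima = mean(peaks$time_of_maximum_h))
  structure(val, policy = policy)
}

#' Weekly storage trajectory of DSC features
#'
#' @param sample_id Free-text sample label.
#' @param storage_temperature Storage temperature in degrees Celsius.
#' @param times_days Sampling times in days, strictly increasing, starting
#'   at the week-0 (pre-storage) measurement.
#' @param features A `data.frame` with one row per time point; must contain
#'   `cryst_enthalpy_J_g` and may contain `cryst_onset_C`, `tg_C`.
#'
#' @return An object of class `storage_record`.
#' @export
storage_record <- function(sample_id, storage_temperature, times_days,
                           features) {
  stopifnot(is.numeric(times_days), is.data.frame(features))
  if (any(diff(times_days) <= 0))
    stop("times_days must be strictly increasing")
  if (nrow(features) != length(times_days))
    stop("features must have one row per time point")
  if (!"cryst_enthalpy_J_g" %in% names(features))
    stop("features must contain a cryst_enthalpy_J_g column")
  structure(list(sample_id = sample_id,
                 storage_temperature = as.numeric(storage_temperature),
                 times_days = as.numeric(times_days), features = features),
            class = "storage_record")
}

#' @export
print.storage_record <- function(x, ...) {
  cat(sprintf("Storage record '%s' at %.4g degC: %d time points over %.4g days\n",
              x$sample_id, x$storage_temperature, length(x$times_days),
              x$times_days[length(x$times_days)]))
  invisible(x)
}

#' Crystallization time from a weekly DSC trajectory
#'
#' Default rule (`"enthalpy_fraction"`): the crystallization time is the
#' first time at which the above-Tg crystallization enthalpy falls below a
#' fraction `theta` of its week-0 value, linearly interpolated between the
#' bracketing measurements. The enthalpy directly tracks the remaining
#' amorphous fraction, so `theta = 0.5` marks half the material
#' crystallized. Alternative rule (`"onset_drop"`): the first time the
#' crystallization onset temperature has dropped by `delta_T` kelvin below
#' its week-0 value (an ongoing-crystallization signature), interpolated
#' the same way.
#'
#' @param record A [storage_record] with at least two time points.
#' @param rule `"enthalpy_fraction"` (default) or `"onset_drop"`.
#' @param theta Enthalpy fraction threshold in (0, 1), default 0.5.
#' @param delta_T Onset drop threshold in K for the alternative rule,
#'   default 5.
#'
#' @return Crystallization time in days (attribute `rule`); 0 when the
#'   sample is already crystalline at week 0 (zero enthalpy); `NA_real_`
#'   when the threshold is never crossed (still amorphous).
#' @examples
#' rec <- storage_record("s", 25, 0:3,
#'   data.frame(cryst_enthalpy_J_g = c(50, 50, 24, 0)))
#' storage_crystallization_time(rec)  # 1 + 25/26 = 1.9615 days
#' @export
storage_crystallization_time <- function(record,
                                         rule = c("enthalpy_fraction",
                                                  "onset_drop"),
                                         theta = 0.5, delta_T = 5) {
  rule <- match.arg(rule)
  stopifnot(inherits(record, "storage_record"))
  tt <- record$times_days
  if (length(tt) < 2L) stop("need at least two weekly feature sets")
  if (rule == "enthalpy_fraction") {
    stopifnot(theta > 0, theta < 1)
    e <- record$features$cryst_enthalpy_J_g
    if (is.na(e[1L])) stop("missing week-0 enthalpy")
    if (e[1L] == 0) return(structure(0, rule = rule))
    level <- theta * e[1L]
    below <- which(!is.na(e) & e < level)
    below <- below[below > 1L]
    if (!length(below)) return(structure(NA_real_, rule = rule))
    k <- below[1L]
    val <- tt[k - 1L] + (e[k - 1L] - level) / (e[k - 1L] - e[k]) *
      (tt[k] - tt[k - 1L])
  } else {
    on <- record$features$cryst_onset_C
    if (is.null(on) || is.na(on[1L])) stop("missing week-0 onset temperature")
    level <- on[1L] - delta_T
    below <- which(!is.na(on) & on < level)
    below <- below[below > 1L]
    if (!length(below)) return(structure(NA_real_, rule = rule))
    k <- below[1L]
    val <- tt[k - 1L] + (on[k - 1L] - level) / (on[k - 1L] - on[k]) *
      (tt[k] - tt[k - 1L])
  }
  structure(as.numeric(val), rule = rule)
}
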