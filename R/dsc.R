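# DSC feature extraction from deconvolved modulated-DSC curves.
#
# Convention: heat flow is exothermic-positive (W/g). The glass transition
# appears on the reversing curve as a downward (endothermic) step of height
# delta_cp * heating_rate; crystallization appears on the total curve as a
# positive exotherm above Tg. Curves arrive already separated into
# reversing/total components; the modulation deconvolution itself is the
# instrument's job and out of scope here.

#' DSC thermogram container
#'
#' @param temperature_C Strictly increasing temperatures in degrees Celsius.
#' @param reversing_W_g Reversing heat-flow signal, W/g, exothermic-positive.
#' @param total_W_g Total heat-flow signal, W/g, exothermic-positive.
#' @param heating_rate Underlying heating rate in K/min (default 2).
#'
#' @return An object of class `dsc_thermogram`.
#' @export
dsc_thermogram <- function(temperature_C, reversing_W_g, total_W_g,
                           heating_rate = 2) {
  stopifnot(is.numeric(temperature_C), is.numeric(reversing_W_g),
            is.numeric(total_W_g))
  if (length(temperature_C) != length(reversing_W_g) ||
      length(temperature_C) != length(total_W_g))
    stop("signals must have the same length as the temperature vector")
  if (any(diff(temperature_C) <= 0))
    stop("temperatures must be strictly increasing")
  if (heating_rate <= 0) stop("heating_rate must be positive")
  structure(list(temperature_C = as.numeric(temperature_C),
                 reversing_W_g = as.numeric(reversing_W_g),
                 total_W_g = as.numeric(total_W_g),
                 heating_rate = as.numeric(heating_rate)),
            class = "dsc_thermogram")
}

#' @export
print.dsc_thermogram <- function(x, ...) {
  cat(sprintf("DSC thermogram: %d points, %.4g .. %.4g degC, %.3g K/min\n",
              length(x$temperature_C), x$temperature_C[1L],
              x$temperature_C[length(x$temperature_C)], x$heating_rate))
  invisible(x)
}

#' Read a thermogram from CSV
#'
#' Fixed dialect: header `temperature_C,reversing_W_per_g,total_W_per_g`.
#'
#' @param path CSV file path.
#' @param heating_rate Heating rate in K/min.
#' @return A [dsc_thermogram].
#' @export
read_dsc_csv <- function(path, heating_rate = 2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "reversing_W_per_g", "total_W_per_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  dsc_thermogram(df$temperature_C, df$reversing_W_per_g, df$total_W_per_g,
                 heating_rate = heating_rate)
}

#' @export
write_dsc_csv <- function(thermogram, path) {
  stopifnot(inherits(thermogram, "dsc_thermogram"))
  df <- data.frame(temperature_C = thermogram$temperature_C,
                   reversing_W_per_g = thermogram$reversing_W_g,
                   total_W_per_g = thermogram$total_W_g)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the glass transition from the reversing curve
#'
#' Locates the endothermic heat-capacity step: linear baselines are fitted
#' before and after the transition region (found from the extreme of the
#' smoothed derivative), the midpoint Tg is the temperature at half the
#' step height between the extrapolated baselines (half-height convention),
#' `delta_cp` is the step height divided by the heating rate, and the onset
#' is the intersection of the pre-transition baseline with the tangent at
#' the steepest slope.
#'
#' @param thermogram A [dsc_thermogram].
#' @param baseline_window Width of each linear-baseline fitting window in K
#'   (default 15).
#' @param baseline_offset Gap between the transition region and each
#'   baseline window in K (default 5).
#' @param smooth_K Smoothing window for the derivative in K (default 0.5).
#'
#' @return A list with `tg_onset`, `tg_midpoint` (degC) and `delta_cp`
#'   (J/(g K)). Errors with "no glass transition found" when no step rises
#'   above the noise.
#' @export
extract_glass_transition <- function(thermogram, baseline_window = 15,
                                     baseline_offset = 5, smooth_K = 0.5) {
  stopifnot(inherits(thermogram, "dsc_thermogram"))
  tt <- thermogram$temperature_C
  y <- thermogram$reversing_W_g
  n <- length(tt)
  if (n < 50L) stop("thermogram too short for glass-transition extraction")
  dT <- stats::median(diff(tt))
  rate_Ks <- thermogram$heating_rate / 60
  ys <- .running_mean(y, round(smooth_K / dT))
  noise <- .noise_sd(y)

  # steepest (endothermic, negative) slope away from the edges
  interior <- seq(max(3L, round(0.02 * n)), min(n - 2L, round(0.98 * n)))
  dy <- c(NA, (ys[3:n] - ys[1:(n - 2L)]) / (tt[3:n] - tt[1:(n - 2L)]), NA)
  istar <- interior[which.max(abs(dy[interior]))]
  slope_star <- dy[istar]

  # transition region: contiguous run around istar with >= 10% of peak slope
  big <- abs(dy) >= 0.1 * abs(slope_star)
  big[is.na(big)] <- FALSE
  lo <- istar; while (lo > 1L && big[lo - 1L]) lo <- lo - 1L
  hi <- istar; while (hi < n && big[hi + 1L]) hi <- hi + 1L
  t_lo <- tt[lo]; t_hi <- tt[hi]

  pre_idx <- which(tt >= t_lo - baseline_offset - baseline_window &
                   tt <= t_lo - baseline_offset)
  post_idx <- which(tt >= t_hi + baseline_offset &
                    tt <= t_hi + baseline_offset + baseline_window)
  if (length(pre_idx) < 10L || length(post_idx) < 10L)
    stop("no glass transition found (insufficient baseline on either side)")
  pre_fit <- stats::lm.fit(cbind(1, tt[pre_idx]), y[pre_idx])$coefficients
  post_fit <- stats::lm.fit(cbind(1, tt[post_idx]), y[post_idx])$coefficients
  pre_line <- function(x) pre_fit[1L] + pre_fit[2L] * x
  post_line <- function(x) post_fit[1L] + post_fit[2L] * x

  step_star <- post_line(tt[istar]) - pre_line(tt[istar])
  if (abs(step_star) < 5 * noise)
    stop("no glass transition found (step below noise threshold)")

  # half-height crossing of the normalised step
  span <- lo:hi
  frac <- (ys[span] - pre_line(tt[span])) /
    (post_line(tt[span]) - pre_line(tt[span]))
  cross <- which(frac[-length(frac)] < 0.5 & frac[-1L] >= 0.5)
  if (!length(cross))
    cross <- which(frac[-length(frac)] >= 0.5 & frac[-1L] < 0.5)
  if (!length(cross)) stop("no glass transition found (no half-height crossing)")
  i <- span[cross[1L]]
  f_i <- (ys[i] - pre_line(tt[i])) / (post_line(tt[i]) - pre_line(tt[i]))
  f_j <- (ys[i + 1L] - pre_line(tt[i + 1L])) /
    (post_line(tt[i + 1L]) - pre_line(tt[i + 1L]))
  tg_mid <- tt[i] + (0.5 - f_i) * (tt[i + 1L] - tt[i]) / (f_j - f_i)

  delta_cp <- abs(post_line(tg_mid) - pre_line(tg_mid)) / rate_Ks

  # onset: pre-baseline x tangent at the steepest slope
  tg_onset <- (ys[istar] - slope_star * tt[istar] - pre_fit[1L]) /
    (pre_fit[2L] - slope_star)
  tg_onset <- as.numeric(tg_onset)
  if (!is.finite(tg_onset) || tg_onset > tg_mid) tg_onset <- tg_mid

  list(tg_onset = tg_onset, tg_midpoint = as.numeric(tg_mid),
       delta_cp = as.numeric(delta_cp))
}

#' Extract the crystallization exotherm from the total curve
#'
#' Finds the dominant exothermic peak, fits a local linear baseline through
#' flank windows just outside the peak extent, and reports the peak
#' temperature, the tangent-intersection onset (leading-edge tangent at the
#' steepest ascending slope crossed with the baseline), and the enthalpy as
#' the baseline-subtracted area divided by the heating rate. Returns zero
#' enthalpy and `NA` temperatures when no peak rises above the noise. With
#' several resolvable exotherms the lowest-temperature one is analysed and
#' a warning is raised.
#'
#' @param thermogram A [dsc_thermogram].
#' @param smooth_K Smoothing window in K used for peak location (default 1).
#' @param flank_K Width of the baseline flank windows in K (default 2).
#' @param min_snr Minimum peak prominence in noise-sd units (default 8).
#'
#' @return A list with `cryst_onset`, `cryst_peak_T` (degC) and
#'   `cryst_enthalpy` (J/g, `>= 0`, zero iff no peak).
#' @export
extract_crystallization_event <- function(thermogram, smooth_K = 1,
                                          flank_K = 2, min_snr = 8) {
  stopifnot(inherits(thermogram, "dsc_thermogram"))
  tt <- thermogram$temperature_C
  y <- thermogram$total_W_g
  n <- length(tt)
  if (n < 50L) stop("thermogram too short for peak extraction")
  dT <- stats::median(diff(tt))
  rate_Ks <- thermogram$heating_rate / 60
  m <- .running_mean(y, round(smooth_K / dT))
  noise <- .noise_sd(y)
  base_level <- stats::median(m)

  pk <- .find_peaks(m, min_prom = max(min_snr * noise, .Machine$double.eps),
                    min_sep = max(3L, round(3 * smooth_K / dT)))
  # discard minor ripples: resolvable peaks carry >= 20% of the main one
  if (nrow(pk) > 1L) pk <- pk[pk$prominence >= 0.2 * max(pk$prominence), ,
                              drop = FALSE]
  if (nrow(pk) == 0L)
    return(list(cryst_onset = NA_real_, cryst_peak_T = NA_real_,
                cryst_enthalpy = 0))
  if (nrow(pk) > 1L) {
    warning("multiple overlapping exotherms detected; analysing the ",
            "lowest-temperature peak")
    pk <- pk[which.min(pk$index), , drop = FALSE]
  }
  ipk <- pk$index[1L]

  # peak extent from half-prominence crossings, extended to ~4 sigma
  half <- m[ipk] - 0.5 * (m[ipk] - base_level)
  below_l <- which(m[seq_len(ipk - 1L)] < half)
  below_r <- which(m[(ipk + 1L):n] < half)
  if (!length(below_l) || !length(below_r))
    return(list(cryst_onset = NA_real_, cryst_peak_T = NA_real_,
                cryst_enthalpy = 0))
  il <- max(below_l); ir <- ipk + min(below_r)
  hw_l <- tt[ipk] - .cross_x(tt, m, il, half)
  hw_r <- .cross_x(tt, m, ir - 1L, half) - tt[ipk]
  t_lo <- max(tt[1L], tt[ipk] - 3.4 * hw_l)
  t_hi <- min(tt[n], tt[ipk] + 3.4 * hw_r)

  fl <- which((tt >= t_lo - flank_K & tt < t_lo) |
              (tt > t_hi & tt <= t_hi + flank_K))
  if (length(fl) < 10L) fl <- which(tt < t_lo | tt > t_hi)
  bl <- stats::lm.fit(cbind(1, tt[fl]), y[fl])$coefficients
  baseline <- function(x) bl[1L] + bl[2L] * x

  inside <- which(tt >= t_lo & tt <= t_hi)
  excess <- y[inside] - baseline(tt[inside])
  area_WK_g <- sum(diff(tt[inside]) *
                   (excess[-1L] + excess[-length(excess)]) / 2)
  enthalpy <- area_WK_g / rate_Ks        # (W/g * K) / (K/s) = J/g
  if (enthalpy < 0) enthalpy <- 0

  # leading-edge tangent onset, on the smoothed rise between t_lo and peak
  rise <- inside[tt[inside] <= tt[ipk]]
  dy <- c(NA, (m[rise][-(1:2)] - m[rise][seq_len(length(rise) - 2L)]) /
            (tt[rise][-(1:2)] - tt[rise][seq_len(length(rise) - 2L)]), NA)
  istar <- rise[which.max(dy)]
  slope <- max(dy, na.rm = TRUE)
  onset <- (m[istar] - slope * tt[istar] - bl[1L]) / (bl[2L] - slope)

  # refine the peak temperature by a quadratic fit around the maximum
  win <- which(abs(tt - tt[ipk]) <= max(2 * dT, 0.25 * (hw_l + hw_r)))
  qf <- stats::lm.fit(cbind(1, tt[win], tt[win]^2), m[win])$coefficients
  peak_T <- if (is.finite(qf[3L]) && qf[3L] < 0)
    -qf[2L] / (2 * qf[3L]) else tt[ipk]
  if (abs(peak_T - tt[ipk]) > (hw_l + hw_r)) peak_T <- tt[ipk]

  list(cryst_onset = as.numeric(onset), cryst_peak_T = as.numeric(peak_T),
       cryst_enthalpy = as.numeric(enthalpy))
}

#' Full feature set of one thermogram
#'
#' Runs [extract_glass_transition] on the reversing curve and
#' [extract_crystallization_event] on the total curve and validates the
#' combined result (onset below midpoint; a detected crystallization peak
#' must sit above Tg).
#'
#' @param thermogram A [dsc_thermogram].
#' @param crystalline_flag Optional boolean carried through (e.g. an XRD
#'   crystallinity call supplied by the user).
#' @param ... Passed to the two extractors.
#'
#' @return An object of class `dsc_features`.
#' @export
dsc_features <- function(thermogram, crystalline_flag = NA, ...) {
  gt <- extract_glass_transition(thermogram)
  ce <- extract_crystallization_event(thermogram)
  out <- structure(c(gt, ce, list(crystalline_flag = crystalline_flag)),
                   class = "dsc_features")
  if (!is.na(out$cryst_onset) && out$cryst_onset < out$tg_midpoint)
    warning("crystallization onset below Tg midpoint; ",
            "check baseline/peak assignment")
  out
}

#' @export
print.dsc_features <- function(x, ...) {
  cat(sprintf("DSC features: Tg onset %.2f / midpoint %.2f degC, dcp %.4g J/(g K)\n",
              x$tg_onset, x$tg_midpoint, x$delta_cp))
  if (is.na(x$cryst_peak_T)) {
    cat("  no crystallization exotherm detected\n")
  } else {
    cat(sprintf("  crystallization: onset %.2f degC, peak %.2f degC, %.4g J/g\n",
                x$cryst_onset, x$cryst_peak_T, x$cryst_enthalpy))
  }
  invisible(x)
}
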