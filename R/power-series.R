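# IMC power-time records: container, CSV I/O, trimming.

#' IMC power-time record
#'
#' A mass-normalised isothermal-microcalorimetry record: strictly increasing
#' times in hours and exothermic-positive power in uW/g, plus acquisition
#' metadata. This is the object every fitting and detection step consumes.
#'
#' @param times_h Times in hours, strictly increasing, first value `>= 0`.
#' @param power_uW_g Power in uW/g, same length as `times_h`.
#' @param sample_id,process,formulation Free-text labels.
#' @param temperature Measurement temperature in degrees Celsius.
#' @param sample_mass_g Sample mass in grams (metadata only; power is
#'   already mass-normalised).
#'
#' @return An object of class `power_time_series` (a list with the fields
#'   above).
#' @export
power_time_series <- function(times_h, power_uW_g, sample_id = NA_character_,
                              process = NA_character_,
                              formulation = NA_character_,
                              temperature = NA_real_, sample_mass_g = NA_real_) {
  stopifnot(is.numeric(times_h), is.numeric(power_uW_g))
  if (length(times_h) != length(power_uW_g))
    stop("times and powers must have the same length")
  if (length(times_h) < 1L) stop("empty record")
  if (times_h[1L] < 0) stop("first time must be >= 0")
  if (any(diff(times_h) <= 0)) {
    bad <- which(diff(times_h) <= 0)[1L] + 1L
    stop("times must be strictly increasing (violated at point ", bad, ")")
  }
  structure(list(times_h = as.numeric(times_h),
                 power_uW_g = as.numeric(power_uW_g),
                 sample_id = sample_id, process = process,
                 formulation = formulation,
                 temperature = as.numeric(temperature),
                 sample_mass_g = as.numeric(sample_mass_g)),
            class = "power_time_series")
}

#' @export
print.power_time_series <- function(x, ...) {
  cat(sprintf("IMC power-time record '%s' (%s / %s)\n",
              x$sample_id, x$process, x$formulation))
  cat(sprintf("  %d points, t = %.4g .. %.4g h, T = %s degC\n",
              length(x$times_h), x$times_h[1L],
              x$times_h[length(x$times_h)],
              format(x$temperature)))
  cat(sprintf("  P(first) = %.4g uW/g, P(last) = %.4g uW/g\n",
              x$power_uW_g[1L], x$power_uW_g[length(x$power_uW_g)]))
  invisible(x)
}

#' @export
length.power_time_series <- function(x) length(x$times_h)

#' @export
as.data.frame.power_time_series <- function(x, ...) {
  data.frame(time_h = x$times_h, power_uW_per_g = x$power_uW_g)
}

#' Trim an IMC record to a fitting window
#'
#' Keeps points with `trim_start <= t <= duration` (hours). The time origin
#' is preserved: times are not re-zeroed, so the MSE model still sees the
#' true elapsed time since the start of the record.
#'
#' @param series A [power_time_series].
#' @param trim_start Start of the window in hours (default 0; the nominal
#'   procedure uses the full record).
#' @param duration End of the window in hours (default 12, the standard
#'   relaxation-measurement duration).
#'
#' @return The trimmed [power_time_series]. Errors if no points remain.
#' @export
preprocess_imc <- function(series, trim_start = 0, duration = 12) {
  stopifnot(inherits(series, "power_time_series"))
  if (trim_start < 0) stop("trim_start must be >= 0")
  if (duration <= trim_start) stop("duration must exceed trim_start")
  keep <- series$times_h >= trim_start & series$times_h <= duration
  if (!any(keep)) stop("trim window [", trim_start, ", ", duration,
                       "] h contains no data points")
  out <- series
  out$times_h <- series$times_h[keep]
  out$power_uW_g <- series$power_uW_g[keep]
  out
}

#' Read an IMC power-time record from CSV
#'
#' Expects the fixed dialect `time_s,power_uW_per_g` (UTF-8, comma
#' separator, '.' decimal) or the same columns with `time_h`. The time unit
#' is never auto-detected: `time_unit` must name the unit of the time
#' column explicitly.
#'
#' @param path CSV file path.
#' @param time_unit `"s"` or `"h"`; must match the file's time column.
#' @param ... Metadata passed to [power_time_series] (sample_id, process,
#'   formulation, temperature, sample_mass_g).
#'
#' @return A [power_time_series] with times converted to hours.
#' @export
read_imc_csv <- function(path, time_unit = c("s", "h"), ...) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- paste0("time_", time_unit)
  if (!tcol %in% names(df))
    stop("column '", tcol, "' not found in ", path,
         " (explicit time unit required; no auto-detection)")
  if (!"power_uW_per_g" %in% names(df))
    stop("column 'power_uW_per_g' not found in ", path)
  tt <- df[[tcol]]
  if (any(!is.finite(tt)) || any(!is.finite(df$power_uW_per_g))) {
    bad <- which(!is.finite(tt) | !is.finite(df$power_uW_per_g))[1L]
    stop("malformed row in ", path, ": data line ", bad)
  }
  if (any(diff(tt) <= 0)) {
    bad <- which(diff(tt) <= 0)[1L] + 1L
    stop("non-monotone time in ", path, ": data line ", bad)
  }
  times_h <- if (time_unit == "s") tt / 3600 else tt
  power_time_series(times_h, df$power_uW_per_g, ...)
}

#' Write an IMC power-time record to CSV
#'
#' Inverse of [read_imc_csv]; writes `time_s,power_uW_per_g` (or `time_h`)
#' with 12 significant digits so that write-read round-trips are lossless
#' at that precision.
#'
#' @param series A [power_time_series].
#' @param path Output CSV path.
#' @param time_unit `"s"` or `"h"` for the written time column.
#' @export
write_imc_csv <- function(series, path, time_unit = c("s", "h")) {
  time_unit <- match.arg(time_unit)
  stopifnot(inherits(series, "power_time_series"))
  tt <- if (time_unit == "s") series$times_h * 3600 else series$times_h
  df <- data.frame(t = format(tt, digits = 12, trim = TRUE, scientific = FALSE),
                   p = format(series$power_uW_g, digits = 12, trim = TRUE))
  names(df) <- c(paste0("time_", time_unit), "power_uW_per_g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sampling grid of the standard IMC acquisition scheme
#'
#' Times (hours) at which the calorimeter logs: every 2 s during the first
#' hour, every 10 s from 1 h to 12 h, and every 60 s beyond 12 h for
#' extended records that wait for a crystallization exotherm. The standard
#' 12 h record has 1800 + 3960 = 5760 points.
#'
#' @param duration_h Record length in hours (default 12).
#' @return Numeric vector of times in hours, starting at the first sampling
#'   interval (2 s).
#' @export
imc_sampling_grid <- function(duration_h = 12) {
  stopifnot(duration_h > 0)
  t1 <- seq(2, min(3600, duration_h * 3600), by = 2)
  t2 <- if (duration_h > 1) seq(3610, min(12 * 3600, duration_h * 3600), by = 10) else numeric(0)
  t3 <- if (duration_h > 12) seq(12 * 3600 + 60, duration_h * 3600, by = 60) else numeric(0)
  c(t1, t2, t3) / 3600
}
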