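#' Default growing-season integration window
#'
#' @param start,end `Date`s (or ISO strings) bounding the season; the end
#'   date is inclusive (integration runs through its midnight-to-midnight
#'   day, i.e. to 24:00 local time of `end`).
#' @return `POSIXct` vector of length 2 (UTC).
#' @export
growing_season <- function(start = "2012-06-16", end = "2012-09-19") {
  c(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
    as.POSIXct(paste(end, "00:00:00"), tz = "UTC") + 86400)
}

#' Integrate seasonal CO2 emission for one collar
#'
#' Drives a fitted respiration model with a collar's continuous temperature
#' and moisture record and integrates the predicted efflux over the growing
#' season by the trapezoidal rule on the half-hourly grid.
#'
#' @param fit a [resp_model].
#' @param series data.frame with columns `timestamp` (`POSIXct`), `T`, `W`
#'   for one collar, nominally at 30-min cadence.
#' @param window length-2 `POSIXct` (or `Date`, end-inclusive) integration
#'   window; defaults to [growing_season()].
#' @param collar_id optional id carried into the result.
#' @return An object of class `emission_estimate`: list with `collar_id`,
#'   `model`, `window`, `total_mol` (mol CO2 m^-2), `total_gC` (g C m^-2)
#'   and `total_gCO2` (g CO2 m^-2).
#' @details Predicted efflux in \eqn{\mu}mol m^-2 s^-1 integrated over
#'   seconds gives \eqn{\mu}mol m^-2; totals are converted with 1e-6 mol per
#'   \eqn{\mu}mol, 12.011 g C and 44.01 g CO2 per mol CO2. Drivers (not the
#'   flux) are linearly interpolated onto a regular 30-min grid spanning the
#'   window, so logger gaps shorter than 24 h are bridged smoothly; a gap
#'   longer than 24 h inside the window, or a window extending beyond the
#'   series span, is an error. A zero-length window integrates to 0.
#' @export
integrate_emission <- function(fit, series, window = growing_season(),
                               collar_id = NA_character_) {
  stopifnot(inherits(fit, "resp_model"))
  window <- as_window(window)
  ts <- parse_timestamp(series$timestamp)
  if (anyNA(ts)) stopf("series has unparseable timestamps")
  o <- order(ts)
  ts <- ts[o]
  emis <- structure(list(collar_id = collar_id, model = fit$model,
                         window = window, total_mol = 0, total_gC = 0,
                         total_gCO2 = 0),
                    class = "emission_estimate")
  if (as.numeric(window[2L]) == as.numeric(window[1L])) return(emis)
  if (window[2L] < window[1L]) stopf("window end precedes window start")
  if (ts[1L] > window[1L] || ts[length(ts)] < window[2L]) {
    stopf("window %s .. %s outside series span %s .. %s",
          format(window[1L]), format(window[2L]), format(ts[1L]), format(ts[length(ts)]))
  }
  inside <- which(ts >= window[1L] & ts <= window[2L])
  span <- range(c(window, ts[inside]))
  gaps <- diff(as.numeric(c(window[1L], ts[inside], window[2L])))
  if (any(gaps > 24 * 3600)) {
    stopf("driver record has a gap exceeding 24 h inside the window")
  }
  tsec <- as.numeric(ts)
  grid <- seq(as.numeric(window[1L]), as.numeric(window[2L]), by = 1800)
  if (grid[length(grid)] < as.numeric(window[2L])) grid <- c(grid, as.numeric(window[2L]))
  Tg <- approx(tsec, series$T[o], xout = grid)$y
  Wg <- approx(tsec, series$W[o], xout = grid)$y
  flux <- predict(fit, T = Tg, W = Wg)  # umol m^-2 s^-1
  total_umol <- pracma::trapz(grid, flux)
  emis$total_mol <- total_umol * 1e-6
  emis$total_gC <- emis$total_mol * GC_PER_MOL
  emis$total_gCO2 <- emis$total_mol * GCO2_PER_MOL
  emis
}

as_window <- function(window) {
  if (inherits(window, "Date")) {
    window <- c(as.POSIXct(paste(window[1L], "00:00:00"), tz = "UTC"),
                as.POSIXct(paste(window[2L], "00:00:00"), tz = "UTC") + 86400)
  }
  if (is.character(window)) window <- as_window(as.Date(window))
  if (!inherits(window, "POSIXct") || length(window) != 2L) {
    stopf("`window` must be two POSIXct instants or two Dates")
  }
  window
}

#' @export
print.emission_estimate <- function(x, ...) {
  cat(sprintf("Seasonal emission%s, model %s, %s .. %s\n",
              if (is.na(x$collar_id)) "" else sprintf(" (collar %s)", x$collar_id),
              x$model, format(x$window[1L]), format(x$window[2L])))
  cat(sprintf("  %.3f mol CO2 m-2 = %.1f g C m-2 = %.1f g CO2 m-2\n",
              x$total_mol, x$total_gC, x$total_gCO2))
  invisible(x)
}

#' Representative diurnal measurement window
#'
#' Finds the time-of-day intervals during which soil respiration stays
#' within a tolerance band around its diurnal mean, computed on the mean
#' diurnal cycle across the supplied days. Chamber surveys scheduled inside
#' these intervals measure fluxes representative of the daily average; the
#' conventional band is +/- 10% of the daily mean.
#'
#' @param series data.frame with columns `timestamp` (`POSIXct`) and `R`
#'   (\eqn{\mu}mol m^-2 s^-1) at uniform cadence covering at least one full
#'   day.
#' @param tolerance half-width of the acceptance band as a fraction of the
#'   diurnal mean (default 0.10).
#' @return An object of class `diurnal_window`: list with `intervals`
#'   (data.frame `start_h`, `end_h`, `width_h`; `end_h < start_h` marks an
#'   interval wrapping midnight), `daily_mean`, `tolerance` and the cycle
#'   resolution `cadence_h`.
#' @details Interval endpoints are the first/last in-band samples of the
#'   mean cycle, so their resolution equals the series cadence. In-band
#'   runs touching both midnight edges are merged into one wrapped
#'   interval.
#' @export
representative_window <- function(series, tolerance = 0.10) {
  ts <- parse_timestamp(series$timestamp)
  if (anyNA(ts)) stopf("series has unparseable timestamps")
  o <- order(ts)
  ts <- ts[o]
  R <- series$R[o]
  if (length(ts) < 2L) stopf("need a series, got %d samples", length(ts))
  dt <- diff(as.numeric(ts))
  if (max(dt) - min(dt) > 1e-6) stopf("series cadence is not uniform")
  cad <- dt[1L]
  per_day <- round(86400 / cad)
  if (per_day * cad != 86400) stopf("cadence must divide the day evenly")
  if (length(R) < per_day) stopf("series covers less than one full day")
  tod <- round((as.numeric(ts) %% 86400) / cad)  # time-of-day bin index
  cyc <- tapply(R, tod, mean)
  if (length(cyc) < per_day) stopf("series does not cover every time of day")
  hours <- as.numeric(names(cyc)) * cad / 3600
  cyc <- as.vector(cyc)
  daily_mean <- mean(cyc)
  inband <- abs(cyc - daily_mean) <= tolerance * abs(daily_mean)
  intervals <- band_intervals(hours, inband)
  structure(list(intervals = intervals, daily_mean = daily_mean,
                 tolerance = tolerance, cadence_h = cad / 3600),
            class = "diurnal_window")
}

# Maximal runs of in-band samples on the circular time-of-day axis.
band_intervals <- function(hours, inband) {
  n <- length(inband)
  if (all(inband)) {
    return(data.frame(start_h = 0, end_h = 24, width_h = 24))
  }
  if (!any(inband)) {
    return(data.frame(start_h = numeric(), end_h = numeric(), width_h = numeric()))
  }
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start_h = hours[starts[keep]], end_h = hours[ends[keep]])
  # merge a run touching 24:00 with one starting at 00:00 (wraps midnight)
  if (length(keep) > 1L && inband[1L] && inband[n]) {
    out$start_h[1L] <- out$start_h[nrow(out)]
    out <- out[-nrow(out), , drop = FALSE]
  }
  out$width_h <- ifelse(out$end_h >= out$start_h,
                        out$end_h - out$start_h,
                        24 - out$start_h + out$end_h)
  rownames(out) <- NULL
  out
}

#' @export
print.diurnal_window <- function(x, ...) {
  cat(sprintf("Diurnal window(s) within +/- %.0f%% of the daily mean (%.2f):\n",
              100 * x$tolerance, x$daily_mean))
  if (!nrow(x$intervals)) {
    cat("  none\n")
  } else {
    for (i in seq_len(nrow(x$intervals))) {
      cat(sprintf("  %05.2f .. %05.2f h (width %.2f h)\n",
                  x$intervals$start_h[i], x$intervals$end_h[i], x$intervals$width_h[i]))
    }
  }
  invisible(x)
}
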