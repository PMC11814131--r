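#' Build a day-of-year percentile climatology
#'
#' For each of the 365 calendar-day slots, all non-missing observations whose
#' slot lies within `window_halfwidth` days (circularly across the year
#' boundary) are pooled across every reference year; the slot mean, standard
#' deviation and requested percentiles are computed on that pool and each
#' statistic is then smoothed with a centred circular moving mean of width
#' `smooth_window`.  This is the windowed-percentile baseline used for marine
#' heatwave / cold-spell detection: an 11-day pooling window
#' (`window_halfwidth = 5`) with ~30-day smoothing.
#'
#' @param series a [daily_series()].
#' @param reference_period integer `c(first_year, last_year)` delimiting the
#'   baseline years; defaults to the full years spanned by `series`.
#' @param percentiles numeric percentiles in (0, 100), e.g. `c(10, 90)` or
#'   `c(8, 92)`.
#' @param window_halfwidth pooling half-window in days (5 gives the 11-day
#'   window).
#' @param smooth_window centred moving-mean width in days; must be odd.  The
#'   default 31 is the odd centred equivalent of a 30-day moving mean.
#' @param percentile_type quantile rule passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#'
#' @return An object of class `climatology`: a list with `day` (1:365),
#'   `mean`, `sd`, `thresholds` (365-row matrix, one column per percentile,
#'   named e.g. `"p90"`), plus the construction parameters and the variable
#'   label carried from `series`.
#' @seealso [climatology_at()], [standardized_anomaly()], [detect_events()]
#' @export
build_climatology <- function(series,
                              reference_period = NULL,
                              percentiles = c(10, 90),
                              window_halfwidth = 5L,
                              smooth_window = 31L,
                              percentile_type = 7L) {
  stopifnot(inherits(series, "daily_series"))
  if (length(percentiles) < 1L || any(percentiles <= 0) || any(percentiles >= 100)) {
    stop("`percentiles` must lie strictly inside (0, 100)", call. = FALSE)
  }
  if (window_halfwidth < 0L) stop("`window_halfwidth` must be >= 0", call. = FALSE)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("`smooth_window` must be a positive odd width (centred window)",
         call. = FALSE)
  }
  years <- as.integer(format(series$date, "%Y"))
  if (is.null(reference_period)) {
    reference_period <- range(years)
  }
  reference_period <- as.integer(reference_period)
  if (reference_period[1L] < min(years) || reference_period[2L] > max(years)) {
    stop("`reference_period` lies outside the span of `series`", call. = FALSE)
  }
  in_ref <- years >= reference_period[1L] & years <= reference_period[2L]
  ref_dates <- series$date[in_ref]
  ref_values <- series$value[in_ref]
  if (as.integer(max(ref_dates) - min(ref_dates)) + 1L < 365L) {
    stop("reference period must cover at least one full year", call. = FALSE)
  }

  slot <- doy_slot(ref_dates)
  ok <- !is.na(ref_values)
  buckets <- split(ref_values[ok], factor(slot[ok], levels = 1:365))

  percentiles <- sort(unique(percentiles))
  p_names <- paste0("p", sub("\\.?0+$", "", formatC(percentiles, format = "f",
                                                    digits = 4)))
  clim_mean <- numeric(365)
  clim_sd <- numeric(365)
  thr <- matrix(NA_real_, 365L, length(percentiles),
                dimnames = list(NULL, p_names))
  offsets <- -window_halfwidth:window_halfwidth
  for (d in 1:365) {
    idx <- ((d - 1L + offsets) %% 365L) + 1L
    pool <- unlist(buckets[idx], use.names = FALSE)
    if (length(pool) == 0L) {
      stop(sprintf("empty climatology pool for calendar-day slot %d", d),
           call. = FALSE)
    }
    clim_mean[d] <- mean(pool)
    clim_sd[d] <- stats::sd(pool)
    if (length(pool) == 1L) clim_sd[d] <- 0
    thr[d, ] <- stats::quantile(pool, probs = percentiles / 100,
                                type = percentile_type, names = FALSE)
  }

  clim_mean <- circular_moving_mean(clim_mean, smooth_window)
  clim_sd <- circular_moving_mean(clim_sd, smooth_window)
  for (j in seq_along(percentiles)) {
    thr[, j] <- circular_moving_mean(thr[, j], smooth_window)
  }

  structure(
    list(day = 1:365,
         mean = clim_mean,
         sd = clim_sd,
         thresholds = thr,
         percentiles = percentiles,
         window_halfwidth = as.integer(window_halfwidth),
         smooth_window = as.integer(smooth_window),
         percentile_type = as.integer(percentile_type),
         reference_period = reference_period,
         variable = series_variable(series)),
    class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf(paste0("<climatology: %s, reference %d-%d, window +/-%d d, ",
                     "smooth %d d, percentiles %s>\n"),
              x$variable, x$reference_period[1L], x$reference_period[2L],
              x$window_halfwidth, x$smooth_window,
              paste(x$percentiles, collapse = "/")))
  invisible(x)
}

# centred moving mean on a 365-slot cycle, circular across the year boundary
circular_moving_mean <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  xx <- c(x[(n - h + 1L):n], x, x[1:h])
  as.numeric(stats::filter(xx, rep(1 / width, width), sides = 2L))[(h + 1L):(h + n)]
}

#' Look up climatology values for calendar dates
#'
#' Returns the slot statistics for each date's calendar day.  The climatology
#' is year-invariant; 29 February maps to the 28 February slot.
#'
#' @param clim a [build_climatology()] result.
#' @param dates `Date` vector.
#' @return A data frame with `date`, `mean`, `sd` and one column per stored
#'   percentile threshold.
#' @export
climatology_at <- function(clim, dates) {
  stopifnot(inherits(clim, "climatology"))
  dates <- as.Date(dates)
  s <- doy_slot(dates)
  out <- data.frame(date = dates, mean = clim$mean[s], sd = clim$sd[s])
  thr <- clim$thresholds[s, , drop = FALSE]
  rownames(thr) <- NULL
  cbind(out, as.data.frame(thr))
}

#' Standardized anomalies against a climatology
#'
#' Computes `(value - climatological mean) / climatological standard
#' deviation` per day; missing values stay missing.
#'
#' @param series a [daily_series()].
#' @param clim a matching [build_climatology()] result.
#' @return A `daily_series` of standardized anomalies (unitless).
#' @export
standardized_anomaly <- function(series, clim) {
  stopifnot(inherits(series, "daily_series"), inherits(clim, "climatology"))
  s <- doy_slot(series$date)
  touched <- unique(s[!is.na(series$value)])
  bad <- touched[clim$sd[touched] == 0]
  if (length(bad) > 0L) {
    stop(sprintf("zero climatological standard deviation on slot(s) %s",
                 paste(utils::head(sort(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  z <- (series$value - clim$mean[s]) / clim$sd[s]
  daily_series(series$date, z, variable = series_variable(series),
               units = "sd units")
}
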