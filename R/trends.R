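#' Count extreme-event days inside a seasonal window
#'
#' Totals the event days of an event table that fall inside the resolved
#' blooming window of a given season year; days of an overlapping event that
#' lie outside the window are not counted.
#'
#' @param events event table from [detect_events()] (columns `start`, `end`).
#' @param window a [blooming_period()].
#' @param season_year labelling year of the window start.
#' @param data_span optional `c(first_date, last_date)` of the underlying
#'   series; if supplied, a window outside it is an error.
#' @return Integer day count.
#' @export
seasonal_event_days <- function(events, window, season_year, data_span = NULL) {
  win <- resolve_period(window, season_year)
  if (!is.null(data_span)) {
    data_span <- as.Date(data_span)
    if (win[2L] < data_span[1L] || win[1L] > data_span[2L]) {
      stop("window lies outside the data span", call. = FALSE)
    }
  }
  if (is.null(events) || nrow(events) == 0L) return(0L)
  s <- pmax(events$start, win[1L])
  e <- pmin(events$end, win[2L])
  keep <- s <= e
  if (!any(keep)) return(0L)
  sum(as.integer(e[keep] - s[keep]) + 1L)
}

#' Decadal linear trend of annual event days
#'
#' Ordinary least-squares regression of event days on season year; the slope
#' is reported per decade (10 x per-year slope) with a two-sided t-test on
#' the slope (n - 2 degrees of freedom).  A series with zero residual
#' variance and zero slope (e.g. constant counts) is reported as slope 0,
#' p = 1 with `degenerate = TRUE` rather than erroring, so flat map pixels
#' survive.
#'
#' @param annual_days data frame with columns `season_year` and `days`
#'   (NA years dropped).
#' @param alpha significance level (default 0.05).
#' @return A list of class `trend_result`: `slope` (days/decade),
#'   `slope_per_year`, `intercept`, `se_slope` (per decade), `t`, `p_value`,
#'   `significant`, `alpha`, `n_years`, `degenerate`.
#' @export
decadal_trend <- function(annual_days, alpha = 0.05) {
  ok <- is.finite(annual_days$days) & is.finite(annual_days$season_year)
  x <- as.numeric(annual_days$season_year[ok])
  y <- as.numeric(annual_days$days[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 years with finite values", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in years", call. = FALSE)
  slope_yr <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope_yr * mean(x)
  resid <- y - intercept - slope_yr * x
  ss_res <- sum(resid^2)
  scale0 <- max(sum((y - mean(y))^2), 1)
  degenerate <- ss_res <= 1e-12 * scale0
  if (degenerate) {
    tstat <- if (abs(slope_yr) <= 1e-12) 0 else Inf
    p <- if (abs(slope_yr) <= 1e-12) 1 else 0
    if (abs(slope_yr) <= 1e-12) slope_yr <- 0
    se_yr <- 0
  } else {
    se_yr <- sqrt(ss_res / (n - 2) / sxx)
    tstat <- slope_yr / se_yr
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(slope = 10 * slope_yr,
                 slope_per_year = slope_yr,
                 intercept = intercept,
                 se_slope = 10 * se_yr,
                 t = tstat,
                 p_value = p,
                 significant = p < alpha,
                 alpha = alpha,
                 n_years = n,
                 degenerate = degenerate),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend: %+.2f days/decade (se %.2f), p = %.3g%s, n = %d>\n",
              x$slope, x$se_slope, x$p_value,
              if (x$significant) " *" else "", x$n_years))
  invisible(x)
}

#' Confidence interval for the decadal slope
#'
#' @param object a [decadal_trend()] result.
#' @param parm ignored (slope only).
#' @param level confidence level.
#' @param ... ignored.
#' @return Numeric `c(lower, upper)` in days/decade.
#' @export
confint.trend_result <- function(object, parm = "slope", level = 0.95, ...) {
  if (object$degenerate) return(c(object$slope, object$slope))
  tq <- stats::qt(1 - (1 - level) / 2, df = object$n_years - 2L)
  c(object$slope - tq * object$se_slope, object$slope + tq * object$se_slope)
}

#' Per-pixel decadal trends on a grid of annual event-day counts
#'
#' @param annual_fields numeric array `[year, lat, lon]` of event-day counts;
#'   `dimnames[[1]]` (or `season_years`) gives the season years.
#' @param season_years integer vector of season years (defaults to the first
#'   dimnames of `annual_fields`).
#' @param alpha significance level.
#' @return A list of class `trend_map` with matrices `slope` (days/decade),
#'   `p_value`, `significant` over `[lat, lon]`; pixels with fewer than 3
#'   finite years are `NA`.
#' @export
trend_map <- function(annual_fields, season_years = NULL, alpha = 0.05) {
  stopifnot(length(dim(annual_fields)) == 3L)
  if (is.null(season_years)) {
    season_years <- as.integer(dimnames(annual_fields)[[1L]])
  }
  stopifnot(length(season_years) == dim(annual_fields)[1L])
  nlat <- dim(annual_fields)[2L]; nlon <- dim(annual_fields)[3L]
  slope <- matrix(NA_real_, nlat, nlon)
  pval <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      y <- annual_fields[, i, j]
      if (sum(is.finite(y)) < 3L) next
      tr <- decadal_trend(data.frame(season_year = season_years, days = y),
                          alpha = alpha)
      slope[i, j] <- tr$slope
      pval[i, j] <- tr$p_value
    }
  }
  structure(list(slope = slope, p_value = pval,
                 significant = pval < alpha, alpha = alpha),
            class = "trend_map")
}
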