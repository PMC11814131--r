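#' Daily time series container
#'
#' A `daily_series` is a data frame with columns `date` and `value` at strict
#' one-day cadence.  Gaps in the input dates are expanded and represented as
#' missing values (`NA`), never as absent rows, so downstream run-length logic
#' can treat "missing" and "non-exceedant" consistently.
#'
#' @param dates `Date` vector, strictly increasing, no duplicates.
#' @param values numeric vector, same length as `dates`; `NA` allowed.
#' @param variable variable label, one of `"sst"`, `"chla"`, `"mld"`, `"other"`.
#' @param units unit string; defaults to the conventional unit for `variable`
#'   (degrees Celsius for SST, mg/m3 for chlorophyll-a, m for MLD).
#'
#' @return A data frame of class `daily_series` with one row per calendar day
#'   from `min(dates)` to `max(dates)` and attributes `variable` and `units`.
#' @export
#' @examples
#' d <- seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day")
#' s <- daily_series(d, 20 + sin(seq_along(d) / 58), variable = "sst")
#' head(s)
daily_series <- function(dates, values,
                         variable = c("sst", "chla", "mld", "other"),
                         units = NULL) {
  variable <- match.arg(variable)
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  if (anyNA(dates)) stop("`dates` must not contain NA", call. = FALSE)
  if (length(dates) != length(values)) {
    stop("`dates` and `values` must have the same length", call. = FALSE)
  }
  if (length(dates) == 0L) stop("empty series", call. = FALSE)
  dd <- diff(as.integer(dates))
  if (any(dd <= 0L)) stop("`dates` must be strictly increasing with no duplicates",
                          call. = FALSE)
  full <- seq(dates[1L], dates[length(dates)], by = "day")
  v <- rep(NA_real_, length(full))
  v[match(dates, full)] <- as.numeric(values)
  if (is.null(units)) {
    units <- switch(variable, sst = "degC", chla = "mg/m3", mld = "m", "")
  }
  out <- data.frame(date = full, value = v)
  attr(out, "variable") <- variable
  attr(out, "units") <- units
  class(out) <- c("daily_series", "data.frame")
  out
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series: %s [%s], %d days (%s..%s), %d missing>\n",
              series_variable(x), attr(x, "units"), nrow(x),
              format(x$date[1L]), format(x$date[nrow(x)]),
              sum(is.na(x$value))))
  invisible(x)
}

series_variable <- function(x) {
  v <- attr(x, "variable")
  if (is.null(v)) "other" else v
}

#' Day-of-year climatology slot for calendar dates
#'
#' Maps dates onto the 365 climatology slots.  29 February shares the
#' 28 February slot (slot 59), the standard convention for day-of-year
#' percentile baselines, so slot 60 is 1 March in every year.
#'
#' @param dates `Date` vector.
#' @return Integer vector of slots in `1..365`.
#' @export
doy_slot <- function(dates) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  yd <- as.POSIXlt(dates)$yday + 1L            # 1-based day of year
  leap <- is_leap_year(as.POSIXlt(dates)$year + 1900L)
  slot <- yd
  slot[leap & yd == 60L] <- 59L                # 29 Feb -> 28 Feb slot
  slot[leap & yd > 60L] <- yd[leap & yd > 60L] - 1L
  slot
}

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Inclusive duration of a date span in days
#'
#' @param start_date,end_date `Date` scalars (or vectors of equal length);
#'   `start_date <= end_date` required.
#' @return Integer day count including both endpoints, leap-year aware.
#' @export
#' @examples
#' duration_days(as.Date("2010-01-04"), as.Date("2010-03-19"))  # 75
duration_days <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (any(end_date < start_date)) {
    stop("`end_date` must not precede `start_date`", call. = FALSE)
  }
  as.integer(end_date - start_date) + 1L
}
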