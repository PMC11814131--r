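#' Regional phytoplankton blooming-period window
#'
#' Defines a region's recurring blooming window by calendar month/day
#' endpoints; windows may cross the year boundary (e.g. October to January).
#'
#' @param region region label (e.g. `"NRS"`, `"NCRS"`, `"SCRS"`, `"SRS"`,
#'   `"basin"`).
#' @param start_month,start_day window start (day defaults to 1).
#' @param end_month,end_day window end; `end_day = NULL` means the last day
#'   of `end_month` in the resolved year.
#' @return A list of class `blooming_period`.
#' @export
blooming_period <- function(region, start_month, end_month,
                            start_day = 1L, end_day = NULL) {
  stopifnot(start_month %in% 1:12, end_month %in% 1:12,
            start_day %in% 1:31)
  if (!is.null(end_day)) stopifnot(end_day %in% 1:31)
  structure(list(region = region,
                 start_month = as.integer(start_month),
                 start_day = as.integer(start_day),
                 end_month = as.integer(end_month),
                 end_day = if (is.null(end_day)) NULL else as.integer(end_day)),
            class = "blooming_period")
}

#' Built-in Red-Sea-style blooming windows
#'
#' The winter windows used throughout the package's examples: NRS January to
#' March, NCRS and SCRS December to February, SRS October to January, and the
#' basin-wide October to March growth period.
#'
#' @return Named list of [blooming_period()] objects.
#' @export
default_blooming_periods <- function() {
  list(NRS   = blooming_period("NRS", 1L, 3L),
       NCRS  = blooming_period("NCRS", 12L, 2L),
       SCRS  = blooming_period("SCRS", 12L, 2L),
       SRS   = blooming_period("SRS", 10L, 1L),
       basin = blooming_period("basin", 10L, 3L))
}

#' Resolve a blooming window to concrete dates
#'
#' Cross-year windows (end month before start month) end in
#' `season_year + 1`; the season is labelled by the year containing the start.
#'
#' @param period a [blooming_period()].
#' @param season_year labelling year (year of the window start).
#' @return `Date` vector `c(start, end)`.
#' @export
#' @examples
#' resolve_period(blooming_period("NRS", 1, 3), 2010)  # 2010-01-01..2010-03-31
#' resolve_period(blooming_period("SRS", 10, 1), 2012) # 2012-10-01..2013-01-31
resolve_period <- function(period, season_year) {
  stopifnot(inherits(period, "blooming_period"))
  season_year <- as.integer(season_year)
  end_year <- season_year + as.integer(period$end_month < period$start_month)
  start <- as.Date(sprintf("%d-%02d-%02d", season_year,
                           period$start_month, period$start_day))
  end_day <- if (is.null(period$end_day)) {
    days_in_month(end_year, period$end_month)
  } else {
    period$end_day
  }
  end <- as.Date(sprintf("%d-%02d-%02d", end_year, period$end_month, end_day))
  if (is.na(start) || is.na(end)) stop("invalid month/day in window", call. = FALSE)
  if (end < start) stop("window resolves to an empty span", call. = FALSE)
  c(start, end)
}

days_in_month <- function(year, month) {
  dim <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- dim[month]
  d[month == 2L & is_leap_year(year)] <- 29L
  d
}

#' Match SST extremes with chlorophyll-a extremes
#'
#' A pair matches as `concurrent` when the two date spans share at least one
#' calendar day, and as `lagged` when the Chl-a event starts between 1 and
#' `max_lag` days after the SST event's end day.  Every qualifying pair is
#' reported; an event may appear in several pairs.
#'
#' @param sst_events,chla_events event tables as returned by
#'   [detect_events()] (columns `polarity`, `start`, `end` are used).
#' @param max_lag maximum delay in days for a lagged match (default 7, the
#'   one-week rule).
#' @return Data frame with `sst_index`, `chla_index`, `sst_polarity`,
#'   `chla_polarity`, `relation` (`"concurrent"`/`"lagged"`) and `direction`
#'   (`"expected"` for MHW/LChl-a or MCS/HChl-a pairs, `"opposite"`
#'   otherwise).
#' @export
match_compounds <- function(sst_events, chla_events, max_lag = 7L) {
  out <- data.frame(sst_index = integer(), chla_index = integer(),
                    sst_polarity = character(), chla_polarity = character(),
                    relation = character(), direction = character(),
                    stringsAsFactors = FALSE)
  if (nrow(sst_events) == 0L || nrow(chla_events) == 0L) return(out)
  for (i in seq_len(nrow(sst_events))) {
    for (j in seq_len(nrow(chla_events))) {
      concurrent <- sst_events$start[i] <= chla_events$end[j] &&
        chla_events$start[j] <= sst_events$end[i]
      lag <- as.integer(chla_events$start[j] - sst_events$end[i])
      lagged <- !concurrent && lag >= 1L && lag <= max_lag
      if (concurrent || lagged) {
        expected <- sst_events$polarity[i] != chla_events$polarity[j]
        out <- rbind(out, data.frame(
          sst_index = i, chla_index = j,
          sst_polarity = sst_events$polarity[i],
          chla_polarity = chla_events$polarity[j],
          relation = if (concurrent) "concurrent" else "lagged",
          direction = if (expected) "expected" else "opposite",
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Classify one blooming period as a compound case
#'
#' Events are first clipped to those overlapping the resolved window by at
#' least one day.  The period classifies as `expected` when at least one
#' match pairs an MHW with a LChl-a event or an MCS with a HChl-a event;
#' `opposite` when matches exist but only in the wrong direction; `sst_only`
#' when SST extremes occur with no matching Chl-a extreme; `none` when no SST
#' extreme overlaps the window.  Precedence is
#' expected > opposite > sst_only > none.  Periods with Chl-a extremes but no
#' SST event are flagged `chl_only`; periods with matches in both directions
#' are flagged `ambiguous`.
#'
#' @param period a [blooming_period()].
#' @param season_year labelling year of the window start.
#' @param sst_events,chla_events event tables from [detect_events()].
#' @param max_lag maximum delay in days (default 7).
#' @return A list of class `compound_case`: `region`, `season_year`,
#'   `window_start`, `window_end`, clipped `sst_events`/`chla_events`,
#'   `matches`, `classification`, `chl_only`, `ambiguous`.
#' @export
classify_blooming_period <- function(period, season_year,
                                     sst_events, chla_events,
                                     max_lag = 7L) {
  win <- resolve_period(period, season_year)
  sst <- clip_events(sst_events, win)
  chl <- clip_events(chla_events, win)
  matches <- match_compounds(sst, chl, max_lag = max_lag)
  has_expected <- any(matches$direction == "expected")
  has_opposite <- any(matches$direction == "opposite")
  classification <- if (nrow(sst) == 0L) {
    "none"
  } else if (has_expected) {
    "expected"
  } else if (has_opposite) {
    "opposite"
  } else {
    "sst_only"
  }
  structure(list(region = period$region,
                 season_year = as.integer(season_year),
                 window_start = win[1L], window_end = win[2L],
                 sst_events = sst, chla_events = chl,
                 matches = matches,
                 classification = classification,
                 chl_only = nrow(sst) == 0L && nrow(chl) > 0L,
                 ambiguous = has_expected && has_opposite),
            class = "compound_case")
}

clip_events <- function(events, win) {
  if (is.null(events) || nrow(events) == 0L) return(event_table_skeleton())
  keep <- events$start <= win[2L] & events$end >= win[1L]
  events[keep, , drop = FALSE]
}

#' Summarize compound cases
#'
#' Counts classifications among cases that contain at least one SST extreme
#' and reports the share that followed the expected response pattern.
#' `chl_only` periods are tracked but excluded from the denominator.
#'
#' @param cases list of [classify_blooming_period()] results.
#' @return A list: `n_cases` (with >= 1 SST event), `counts` (named vector
#'   over expected/opposite/sst_only/none), `n_chl_only`,
#'   `percent_expected` (unrounded) and `percent_expected_rounded`.
#' @export
summarize_cases <- function(cases) {
  if (length(cases) == 0L) stop("no cases to summarize", call. = FALSE)
  cls <- vapply(cases, function(x) x$classification, character(1))
  counts <- table(factor(cls, levels = c("expected", "opposite",
                                         "sst_only", "none")))
  with_sst <- cls != "none"
  n_cases <- sum(with_sst)
  pct <- if (n_cases > 0L) 100 * sum(cls == "expected") / n_cases else NA_real_
  list(n_cases = n_cases,
       counts = c(counts),
       n_chl_only = sum(vapply(cases, function(x) isTRUE(x$chl_only), logical(1))),
       percent_expected = pct,
       percent_expected_rounded = if (is.na(pct)) NA_real_ else round(pct))
}

#' Compound cases as a table
#'
#' Flattens a list of [classify_blooming_period()] results into the
#' one-row-per-period case table (the shape used for supplementary-style
#' case listings).
#'
#' @param cases list of `compound_case` objects.
#' @return Data frame with region, season year, window, event counts by type,
#'   number of matches, classification and flags.
#' @export
cases_table <- function(cases) {
  do.call(rbind, lapply(cases, function(x) {
    data.frame(region = x$region,
               season_year = x$season_year,
               window_start = x$window_start,
               window_end = x$window_end,
               n_mhw = sum(x$sst_events$polarity == "high"),
               n_mcs = sum(x$sst_events$polarity == "low"),
               n_hchl = sum(x$chla_events$polarity == "high"),
               n_lchl = sum(x$chla_events$polarity == "low"),
               n_matches = nrow(x$matches),
               classification = x$classification,
               chl_only = x$chl_only,
               ambiguous = x$ambiguous,
               stringsAsFactors = FALSE)
  }))
}
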