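#' Detection parameters for extreme events
#'
#' Bundles the threshold percentile, minimum duration, gap-joining width and
#' comparison rule used by [detect_events()].  Conventional settings:
#' trend-mode SST uses the 90th/10th percentile with a 5-day minimum; the
#' stricter compound-mode SST uses 92nd/8th with a 10-day minimum; Chl-a
#' extremes use 90th/10th with a 3-day minimum and no gap joining.
#'
#' @param percentile upper threshold percentile (the lower threshold is
#'   `100 - percentile`), e.g. 90 or 92.
#' @param min_duration minimum run length in days (>= 1).
#' @param max_gap maximum number of non-exceedant days between qualifying
#'   runs that are merged into one event (>= 0).
#' @param comparison `"strict"` (value must exceed the threshold, the
#'   default) or `"inclusive"` (equality counts as exceedance).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(percentile = 90, min_duration = 5L,
                             max_gap = 2L, comparison = c("strict", "inclusive")) {
  comparison <- match.arg(comparison)
  if (percentile <= 50 || percentile >= 100) {
    stop("`percentile` must be the upper percentile in (50, 100)", call. = FALSE)
  }
  if (min_duration < 1L) stop("`min_duration` must be >= 1", call. = FALSE)
  if (max_gap < 0L) stop("`max_gap` must be >= 0", call. = FALSE)
  structure(list(percentile = percentile,
                 min_duration = as.integer(min_duration),
                 max_gap = as.integer(max_gap),
                 comparison = comparison),
            class = "detection_params")
}

#' Standard parameter sets
#'
#' @return [detection_params()] presets: `params_sst_trend()` (90th/10th,
#'   >= 5 days, 2-day gap joining), `params_sst_compound()` (92nd/8th,
#'   >= 10 days, 2-day gap joining), `params_chla()` (90th/10th, >= 3 days,
#'   no gap joining).
#' @rdname detection_presets
#' @export
params_sst_trend <- function() detection_params(90, 5L, 2L)

#' @rdname detection_presets
#' @export
params_sst_compound <- function() detection_params(92, 10L, 2L)

#' @rdname detection_presets
#' @export
params_chla <- function() detection_params(90, 3L, 0L)

#' Detect extreme events in a daily series
#'
#' Marks each day exceedant when its value crosses the calendar-day threshold
#' (above the upper percentile for `polarity = "high"`, below the lower
#' percentile for `"low"`; missing days are never exceedant), keeps maximal
#' exceedance runs of at least `min_duration` days, then merges qualifying
#' runs separated by at most `max_gap` non-exceedant days into single events
#' spanning the outer boundaries.  Intensity metrics are computed on the
#' merged span relative to the climatological mean.
#'
#' Runs truncated by the series boundary still count if their observed length
#' reaches `min_duration`; such events carry `edge = TRUE`.
#'
#' @param series a [daily_series()].
#' @param clim a [build_climatology()] result for the same variable, holding
#'   the needed percentiles.
#' @param params a [detection_params()].
#' @param polarity `"both"` (default), `"high"` or `"low"`.
#' @return A data frame with one row per event: `variable`, `polarity`,
#'   `start`, `end`, `duration`, `max_intensity`, `mean_intensity`,
#'   `cumulative_intensity`, `peak_date`, `n_missing`, `edge`; chronological
#'   and non-overlapping within each polarity.
#' @export
detect_events <- function(series, clim, params = params_sst_trend(),
                          polarity = c("both", "high", "low")) {
  stopifnot(inherits(series, "daily_series"), inherits(clim, "climatology"),
            inherits(params, "detection_params"))
  polarity <- match.arg(polarity)
  if (series_variable(series) != clim$variable) {
    stop(sprintf("series variable '%s' does not match climatology variable '%s'",
                 series_variable(series), clim$variable), call. = FALSE)
  }
  want <- if (polarity == "both") c("high", "low") else polarity
  out <- do.call(rbind, lapply(want, function(p) {
    detect_one_polarity(series, clim, params, p)
  }))
  out[order(out$start, out$polarity), , drop = FALSE]
}

detect_one_polarity <- function(series, clim, params, polarity) {
  p_up <- params$percentile
  p_lo <- 100 - p_up
  pct <- if (polarity == "high") p_up else p_lo
  j <- match(pct, clim$percentiles)
  if (is.na(j)) {
    stop(sprintf("climatology does not hold the %gth percentile", pct),
         call. = FALSE)
  }
  slot <- doy_slot(series$date)
  thr <- clim$thresholds[slot, j]
  v <- series$value
  mask <- if (polarity == "high") {
    if (params$comparison == "strict") v > thr else v >= thr
  } else {
    if (params$comparison == "strict") v < thr else v <= thr
  }
  mask[is.na(mask)] <- FALSE

  runs <- exceedance_runs(mask, params$min_duration)
  spans <- merge_runs(runs, params$max_gap)
  empty <- event_table_skeleton()
  if (nrow(spans) == 0L) return(empty)

  n <- nrow(series)
  rows <- lapply(seq_len(nrow(spans)), function(k) {
    i0 <- spans$start[k]; i1 <- spans$end[k]
    m <- event_metrics(series, clim,
                       span = c(series$date[i0], series$date[i1]),
                       polarity = polarity)
    data.frame(variable = series_variable(series),
               polarity = polarity,
               start = series$date[i0],
               end = series$date[i1],
               duration = m$duration,
               max_intensity = m$max_intensity,
               mean_intensity = m$mean_intensity,
               cumulative_intensity = m$cumulative_intensity,
               peak_date = m$peak_date,
               n_missing = m$n_missing,
               edge = (i0 == 1L) || (i1 == n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

event_table_skeleton <- function() {
  data.frame(variable = character(), polarity = character(),
             start = as.Date(character()), end = as.Date(character()),
             duration = integer(), max_intensity = numeric(),
             mean_intensity = numeric(), cumulative_intensity = numeric(),
             peak_date = as.Date(character()), n_missing = integer(),
             edge = logical(), stringsAsFactors = FALSE)
}

# maximal TRUE-runs of length >= min_duration, as index spans
exceedance_runs <- function(mask, min_duration) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  data.frame(start = starts[keep], end = ends[keep])
}

# merge qualifying runs separated by <= max_gap days (filter-then-merge order)
merge_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1L || max_gap == 0L) return(runs)
  out_s <- integer(0); out_e <- integer(0)
  cs <- runs$start[1L]; ce <- runs$end[1L]
  for (k in seq_len(nrow(runs))[-1L]) {
    gap <- runs$start[k] - ce - 1L
    if (gap <= max_gap) {
      ce <- runs$end[k]
    } else {
      out_s <- c(out_s, cs); out_e <- c(out_e, ce)
      cs <- runs$start[k]; ce <- runs$end[k]
    }
  }
  data.frame(start = c(out_s, cs), end = c(out_e, ce))
}

#' Intensity metrics over a date span
#'
#' Intensity on each day is `value - climatological mean` for that calendar
#' day.  `max_intensity` is the signed extreme (most positive for high
#' polarity, most negative for low), `mean_intensity` and
#' `cumulative_intensity` are taken over all non-missing days of the span
#' (merged-gap days included); the count of missing days is reported.
#'
#' @param series a [daily_series()].
#' @param clim a [build_climatology()] result.
#' @param span `c(start_date, end_date)` within the series.
#' @param polarity `"high"` or `"low"`.
#' @return A list: `duration`, `max_intensity`, `mean_intensity`,
#'   `cumulative_intensity`, `peak_date`, `n_missing`.
#' @export
event_metrics <- function(series, clim, span, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  span <- as.Date(span)
  if (span[1L] > span[2L]) stop("reversed span", call. = FALSE)
  if (span[1L] < series$date[1L] || span[2L] > series$date[nrow(series)]) {
    stop("span outside the series", call. = FALSE)
  }
  sel <- series$date >= span[1L] & series$date <= span[2L]
  d <- series$date[sel]
  intensity <- series$value[sel] - clim$mean[doy_slot(d)]
  ok <- !is.na(intensity)
  if (!any(ok)) {
    return(list(duration = duration_days(span[1L], span[2L]),
                max_intensity = NA_real_, mean_intensity = NA_real_,
                cumulative_intensity = NA_real_, peak_date = as.Date(NA),
                n_missing = sum(!ok)))
  }
  peak_i <- if (polarity == "high") which.max(replace(intensity, !ok, -Inf))
            else which.min(replace(intensity, !ok, Inf))
  list(duration = duration_days(span[1L], span[2L]),
       max_intensity = intensity[peak_i],
       mean_intensity = mean(intensity[ok]),
       cumulative_intensity = sum(intensity[ok]),
       peak_date = d[peak_i],
       n_missing = sum(!ok))
}
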