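#' Daily gridded field
#'
#' In-memory container for a daily field over a latitude/longitude grid.
#'
#' @param times `Date` vector of daily time steps.
#' @param lats,lons monotone coordinate vectors, decimal degrees.
#' @param values numeric array `[time, lat, lon]`; `NA` for missing/land.
#' @param variable `"sst"` or `"chla"`.
#' @param units unit string (defaults by variable).
#' @return A list of class `gridded_field`.
#' @export
gridded_field <- function(times, lats, lons, values,
                          variable = c("sst", "chla"), units = NULL) {
  variable <- match.arg(variable)
  times <- as.Date(times)
  stopifnot(length(dim(values)) == 3L,
            dim(values)[1L] == length(times),
            dim(values)[2L] == length(lats),
            dim(values)[3L] == length(lons))
  if (is.unsorted(lats) && is.unsorted(rev(lats))) {
    stop("`lats` must be monotone", call. = FALSE)
  }
  if (is.unsorted(lons) && is.unsorted(rev(lons))) {
    stop("`lons` must be monotone", call. = FALSE)
  }
  if (is.null(units)) units <- if (variable == "sst") "degC" else "mg/m3"
  structure(list(times = times, lats = as.numeric(lats),
                 lons = as.numeric(lons), values = values,
                 variable = variable, units = units),
            class = "gridded_field")
}

resolve_mask <- function(field, mask) {
  if (is.null(mask)) {
    mask <- matrix(TRUE, length(field$lats), length(field$lons))
  }
  stopifnot(is.logical(mask),
            nrow(mask) == length(field$lats),
            ncol(mask) == length(field$lons))
  if (!any(mask)) stop("empty region mask", call. = FALSE)
  mask
}

#' Spatial mean of a gridded field over a region
#'
#' Unweighted mean over valid in-mask pixels per day (optionally
#' cos(latitude)-weighted); a day with no valid pixel is missing.
#'
#' @param field a [gridded_field()].
#' @param mask logical `[lat, lon]` region mask (`NULL` = whole grid).
#' @param weighting `"none"` (default) or `"coslat"`.
#' @return A [daily_series()] of the field's variable.
#' @export
spatial_mean <- function(field, mask = NULL, weighting = c("none", "coslat")) {
  stopifnot(inherits(field, "gridded_field"))
  weighting <- match.arg(weighting)
  mask <- resolve_mask(field, mask)
  w <- if (weighting == "coslat") {
    matrix(cos(field$lats * pi / 180), length(field$lats), length(field$lons))
  } else {
    matrix(1, length(field$lats), length(field$lons))
  }
  w[!mask] <- NA_real_
  nt <- length(field$times)
  out <- vapply(seq_len(nt), function(t) {
    v <- field$values[t, , ]
    ok <- !is.na(v) & !is.na(w)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
  daily_series(field$times, out, variable = field$variable,
               units = field$units)
}

#' Fill interior gaps of a daily series by linear interpolation
#'
#' Leading and trailing missing days are left missing.
#'
#' @param series a [daily_series()].
#' @return A `daily_series` with interior `NA` runs linearly interpolated
#'   in time.
#' @export
interpolate_gaps <- function(series) {
  stopifnot(inherits(series, "daily_series"))
  v <- zoo::na.approx(series$value, x = as.numeric(series$date), na.rm = FALSE)
  daily_series(series$date, v, variable = series_variable(series),
               units = attr(series, "units"))
}

#' Quality-control and spatially average a chlorophyll-a field
#'
#' Per day: pixels above `max_value` are masked as false extremes; spatial
#' coverage is the share of valid in-mask pixels; days with coverage below
#' `min_coverage` are dropped (coverage exactly at the limit is kept);
#' remaining days are spatially averaged and interior gaps of the resulting
#' series are filled by linear interpolation in time.
#'
#' @param field a [gridded_field()] with `variable = "chla"`.
#' @param mask logical region mask (`NULL` = whole grid).
#' @param min_coverage minimum valid-pixel share to keep a day (default 0.30).
#' @param max_value concentration cap in mg/m3 (default 10).
#' @return A [daily_series()] of regional Chl-a with attribute `coverage`
#'   (per-day share of valid pixels).
#' @export
preprocess_chla <- function(field, mask = NULL, min_coverage = 0.30,
                            max_value = 10) {
  stopifnot(inherits(field, "gridded_field"))
  if (field$variable != "chla") {
    stop("`field` must hold chlorophyll-a", call. = FALSE)
  }
  mask <- resolve_mask(field, mask)
  n_region <- sum(mask)
  nt <- length(field$times)
  means <- numeric(nt)
  coverage <- numeric(nt)
  for (t in seq_len(nt)) {
    v <- field$values[t, , ][mask]
    v[!is.na(v) & v > max_value] <- NA_real_
    coverage[t] <- sum(!is.na(v)) / n_region
    means[t] <- if (coverage[t] >= min_coverage) mean(v, na.rm = TRUE)
                else NA_real_
  }
  s <- daily_series(field$times, means, variable = "chla")
  s <- interpolate_gaps(s)
  attr(s, "coverage") <- coverage
  s
}

#' Read a region / blooming-window configuration
#'
#' Parses a flat YAML file mapping region labels to latitude/longitude
#' bounds and blooming windows, e.g.
#' ```yaml
#' regions:
#'   NRS: {lat: [25.5, 28.5], lon: [32, 39], bloom: [1, 3]}
#' ```
#' where `bloom` is `(start_month, end_month)`.
#'
#' @param path YAML file path.
#' @return A named list per region with `lat`, `lon` bounds and a
#'   [blooming_period()] `bloom`.
#' @export
read_region_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) stop("config has no `regions` section", call. = FALSE)
  lapply_names(cfg$regions, function(r, name) {
    list(lat = as.numeric(r$lat), lon = as.numeric(r$lon),
         bloom = blooming_period(name, r$bloom[[1L]], r$bloom[[2L]]))
  })
}

lapply_names <- function(x, f) {
  out <- mapply(f, x, names(x), SIMPLIFY = FALSE)
  names(out) <- names(x)
  out
}

#' @rdname series_csv
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(data.frame(date = format(series$date),
                              value = series$value),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a daily series as CSV
#'
#' Two-column `date,value` CSV; empty values are missing days.
#'
#' @param series a [daily_series()] (for writing).
#' @param path file path.
#' @param variable variable label for the series read back.
#' @return The series ([read_series_csv()]) or the path, invisibly.
#' @name series_csv
#' @export
read_series_csv <- function(path, variable = "other") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  daily_series(as.Date(d$date), as.numeric(d$value), variable = variable)
}

#' Write an event table as CSV
#'
#' One row per detected event with a parameter fingerprint recorded in a
#' leading comment line.
#'
#' @param events event table from [detect_events()].
#' @param path file path.
#' @param params the [detection_params()] used (for the fingerprint).
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("# params: percentile=%g min_duration=%d max_gap=%d comparison=%s",
                       params$percentile, params$min_duration,
                       params$max_gap, params$comparison), con)
  }
  df <- events
  df$start <- format(df$start); df$end <- format(df$end)
  df$peak_date <- format(df$peak_date)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a climatology as CSV
#'
#' One row per calendar-day slot: `slot, mean, sd` plus one column per
#' stored percentile.
#'
#' @param clim a [build_climatology()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_climatology_csv <- function(clim, path) {
  df <- data.frame(slot = clim$day, mean = clim$mean, sd = clim$sd)
  df <- cbind(df, as.data.frame(clim$thresholds))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full synthetic-scenario pipeline
#'
#' Simulates a scenario, builds climatologies, detects SST extremes in trend
#' and compound mode, detects Chl-a extremes on the gap-interpolated series,
#' classifies blooming periods, fits the decadal trend of seasonal event
#' days, computes MLD records on scenario profiles, and writes every
#' artifact as CSV.  Deterministic given the scenario seed.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @param region label of the blooming window to use (a name of
#'   [default_blooming_periods()], default `"basin"`).
#' @param max_lag compound matching lag in days.
#' @return Invisibly, a list with the computed objects and the paths of the
#'   written artifacts.
#' @export
run_pipeline <- function(config, out_dir, region = "basin", max_lag = 7L) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    sst <- generate_sst(config)
    chla <- generate_chla(config, sst$truth)
    list(sst = sst, chla = chla)
  })
  chla_filled <- stage("preprocess", interpolate_gaps(sim$chla))

  clims <- stage("climatology", {
    ref <- c(config$start_year, config$start_year + config$n_years - 1L)
    list(sst = build_climatology(sim$sst$series, reference_period = ref,
                                 percentiles = c(8, 10, 90, 92)),
         chla = build_climatology(chla_filled, reference_period = ref,
                                  percentiles = c(10, 90)))
  })

  events <- stage("detect", {
    list(sst_trend = detect_events(sim$sst$series, clims$sst, params_sst_trend()),
         sst_compound = detect_events(sim$sst$series, clims$sst,
                                      params_sst_compound()),
         chla = detect_events(chla_filled, clims$chla, params_chla()))
  })

  window <- default_blooming_periods()[[region]]
  years <- config$start_year:(config$start_year + config$n_years - 1L)
  season_years <- years[vapply(years, function(y) {
    win <- resolve_period(window, y)
    win[1L] >= sim$sst$series$date[1L] &&
      win[2L] <= sim$sst$series$date[nrow(sim$sst$series)]
  }, logical(1))]

  cases <- stage("compound", lapply(season_years, function(y) {
    classify_blooming_period(window, y, events$sst_compound, events$chla,
                             max_lag = max_lag)
  }))

  trend <- stage("trend", {
    days <- vapply(season_years, function(y) {
      seasonal_event_days(events$sst_trend[events$sst_trend$polarity == "high", ],
                          window, y)
    }, numeric(1))
    annual <- data.frame(season_year = season_years, days = days)
    list(annual = annual,
         fit = if (length(season_years) >= 3L) decadal_trend(annual) else NULL)
  })

  mld <- stage("mld", {
    depths <- seq(0, 200, by = 5)
    profs <- lapply(c(40, 60, 80), function(m) {
      generate_profile(30, m, 0.1, depths)
    })
    lapply(profs, compute_mld)
  })

  paths <- stage("write", {
    p <- list(
      sst_series = file.path(out_dir, "sst_series.csv"),
      chla_series = file.path(out_dir, "chla_series.csv"),
      events_sst_trend = file.path(out_dir, "events_sst_trend.csv"),
      events_sst_compound = file.path(out_dir, "events_sst_compound.csv"),
      events_chla = file.path(out_dir, "events_chla.csv"),
      cases = file.path(out_dir, "cases.csv"),
      trend = file.path(out_dir, "trend_annual_days.csv"),
      mld = file.path(out_dir, "mld_records.csv"),
      truth = file.path(out_dir, "truth_events.csv"),
      params = file.path(out_dir, "params.yml"))
    write_series_csv(sim$sst$series, p$sst_series)
    write_series_csv(sim$chla, p$chla_series)
    write_events_csv(events$sst_trend, p$events_sst_trend, params_sst_trend())
    write_events_csv(events$sst_compound, p$events_sst_compound,
                     params_sst_compound())
    write_events_csv(events$chla, p$events_chla, params_chla())
    ct <- cases_table(cases)
    ct$window_start <- format(ct$window_start)
    ct$window_end <- format(ct$window_end)
    utils::write.csv(ct, p$cases, row.names = FALSE, quote = FALSE)
    utils::write.csv(trend$annual, p$trend, row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(
      date = format(vapply(mld, function(r) as.character(r$date), character(1))),
      mld = vapply(mld, function(r) r$mld, numeric(1)),
      flag = vapply(mld, function(r) r$method_flag, character(1))),
      p$mld, row.names = FALSE, quote = FALSE)
    tr <- sim$sst$truth$events
    tr$start <- format(tr$start); tr$end <- format(tr$end)
    utils::write.csv(tr, p$truth, row.names = FALSE, quote = FALSE)
    cfg_echo <- config
    cfg_echo$injected_events <- lapply(config$injected_events, function(ev) {
      list(polarity = ev$polarity, start_date = format(ev$start_date),
           duration = ev$duration, amplitude = ev$amplitude,
           chla_response_sign = ev$chla_response_sign,
           chla_response_amp = ev$chla_response_amp)
    })
    yaml::write_yaml(unclass(cfg_echo), p$params)
    p
  })

  invisible(list(series = list(sst = sim$sst$series, chla = sim$chla,
                               chla_filled = chla_filled),
                 truth = sim$sst$truth,
                 climatologies = clims, events = events, cases = cases,
                 trend = trend, mld = mld, paths = paths))
}
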