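#' Synthetic scenario configuration
#'
#' Describes a multi-year daily SST / chlorophyll-a scenario: a seasonal SST
#' cycle with AR(1) noise and an optional warming trend, a winter Chl-a bloom
#' with multiplicative lognormal noise, missing days and rare outliers, and a
#' set of injected warm/cold episodes with lagged, sign-opposed Chl-a
#' responses.  The generated data emulate the statistical structure of
#' spatially averaged satellite SST and ocean-colour series so every
#' downstream stage can be tested against known ground truth.
#'
#' @param n_years number of full years (>= 1).
#' @param start_year first calendar year of the time axis.
#' @param seasonal_mean_sst annual-mean SST, degrees C.
#' @param seasonal_amp_sst amplitude of the seasonal SST cycle, degrees C
#'   (peak in late summer).
#' @param ar1_coef lag-1 autocorrelation of the SST residuals, in `[0, 1)`.
#' @param noise_sd marginal standard deviation of the SST residuals,
#'   degrees C (>= 0; 0 gives the deterministic limit).
#' @param warming_trend linear SST trend, degrees C per decade.
#' @param injected_events list of [injected_event()] objects.
#' @param chla_base background Chl-a level, mg/m3 (> 0).
#' @param chla_bloom_amp amplitude of the winter bloom above `chla_base`,
#'   mg/m3 (>= 0).
#' @param chla_bloom_peak_doy calendar day of the bloom peak (default 15,
#'   mid-January).
#' @param chla_bloom_width_days Gaussian width of the bloom in days.
#' @param chla_noise_cv coefficient of variation of the multiplicative
#'   lognormal Chl-a noise (>= 0).
#' @param coupling_lag_days delay of the Chl-a response behind an injected
#'   SST episode, days (>= 0).
#' @param missing_fraction fraction of Chl-a days set missing, in `[0, 1)`.
#' @param outlier_rate per-day probability of replacing a Chl-a value with a
#'   spike drawn uniformly in (10, 20] mg/m3, exercising the quality-control
#'   cap.
#' @param seed integer seed; equal seeds give bit-identical scenarios.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 21L,
                            start_year = 1998L,
                            seasonal_mean_sst = 26,
                            seasonal_amp_sst = 3,
                            ar1_coef = 0.7,
                            noise_sd = 0.4,
                            warming_trend = 0,
                            injected_events = list(),
                            chla_base = 0.2,
                            chla_bloom_amp = 0.4,
                            chla_bloom_peak_doy = 15L,
                            chla_bloom_width_days = 40,
                            chla_noise_cv = 0.25,
                            coupling_lag_days = 3L,
                            missing_fraction = 0.05,
                            outlier_rate = 0,
                            seed = 1L) {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  chk(n_years >= 1, "n_years", "must be >= 1")
  chk(ar1_coef >= 0 && ar1_coef < 1, "ar1_coef", "must lie in [0, 1)")
  chk(noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(chla_base > 0, "chla_base", "must be > 0")
  chk(chla_bloom_amp >= 0, "chla_bloom_amp", "must be >= 0")
  chk(chla_noise_cv >= 0, "chla_noise_cv", "must be >= 0")
  chk(coupling_lag_days >= 0, "coupling_lag_days", "must be >= 0")
  chk(missing_fraction >= 0 && missing_fraction < 1, "missing_fraction",
      "must lie in [0, 1)")
  chk(outlier_rate >= 0 && outlier_rate < 1, "outlier_rate",
      "must lie in [0, 1)")
  for (ev in injected_events) {
    if (!inherits(ev, "injected_event")) {
      stop("invalid `injected_events`: entries must be injected_event()",
           call. = FALSE)
    }
  }
  structure(as.list(environment())[c(
    "n_years", "start_year", "seasonal_mean_sst", "seasonal_amp_sst",
    "ar1_coef", "noise_sd", "warming_trend", "injected_events",
    "chla_base", "chla_bloom_amp", "chla_bloom_peak_doy",
    "chla_bloom_width_days", "chla_noise_cv", "coupling_lag_days",
    "missing_fraction", "outlier_rate", "seed")],
    class = "scenario_config")
}

#' Injected warm/cold episode with a coupled Chl-a response
#'
#' A warm episode raises SST by `amplitude` over its span and, under the
#' expected stratification response, suppresses Chl-a
#' (`chla_response_sign = -1`, multiplicative factor < 1); a cold episode
#' lowers SST and elevates Chl-a.  The Chl-a response is applied to the mean
#' level (additively in log space), shifted by the scenario's coupling lag.
#'
#' @param polarity `"warm"` or `"cold"`.
#' @param start_date first day of the episode.
#' @param duration length in days (>= 1).
#' @param amplitude SST offset in degrees C (> 0; sign comes from polarity).
#' @param chla_response_sign -1 (suppressed), 0 (none) or +1 (elevated);
#'   defaults to the expected pattern for the polarity.
#' @param chla_response_amp multiplicative factor on the Chl-a mean level
#'   over the lagged span (> 0); defaults to 0.5 for suppression and 2 for
#'   elevation.
#' @return A list of class `injected_event`.
#' @export
injected_event <- function(polarity = c("warm", "cold"),
                           start_date, duration, amplitude,
                           chla_response_sign = NULL,
                           chla_response_amp = NULL) {
  polarity <- match.arg(polarity)
  if (duration < 1) stop("invalid `duration`: must be >= 1", call. = FALSE)
  if (amplitude <= 0) stop("invalid `amplitude`: must be > 0", call. = FALSE)
  if (is.null(chla_response_sign)) {
    chla_response_sign <- if (polarity == "warm") -1L else 1L
  }
  if (!chla_response_sign %in% c(-1L, 0L, 1L)) {
    stop("invalid `chla_response_sign`: must be -1, 0 or +1", call. = FALSE)
  }
  if (is.null(chla_response_amp)) {
    chla_response_amp <- if (chla_response_sign < 0) 0.5
                         else if (chla_response_sign > 0) 2 else 1
  }
  if (chla_response_amp <= 0) {
    stop("invalid `chla_response_amp`: must be > 0", call. = FALSE)
  }
  structure(list(polarity = polarity,
                 start_date = as.Date(start_date),
                 duration = as.integer(duration),
                 amplitude = amplitude,
                 chla_response_sign = as.integer(chla_response_sign),
                 chla_response_amp = chla_response_amp),
            class = "injected_event")
}

scenario_dates <- function(config) {
  seq(as.Date(sprintf("%d-01-01", config$start_year)),
      as.Date(sprintf("%d-12-31", config$start_year + config$n_years - 1L)),
      by = "day")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_scenario_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

seasonal_sst_cycle <- function(config, slot) {
  # late-summer peak (slot 227 ~ mid-August)
  config$seasonal_mean_sst +
    config$seasonal_amp_sst * cos(2 * pi * (slot - 227) / 365)
}

#' Generate a synthetic daily SST series
#'
#' Seasonal cycle plus linear warming trend plus AR(1) Gaussian residuals
#' with marginal standard deviation `noise_sd`; injected warm (cold)
#' episodes raise (lower) the values by their amplitude over their exact
#' span.  Identical seeds give bit-identical output.
#'
#' @param config a [scenario_config()].
#' @return A list: `series` (a [daily_series()] of SST) and `truth` (list
#'   with `events`, a data frame of realized episode spans, and the
#'   scenario's time axis range).
#' @export
generate_sst <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  dates <- scenario_dates(config)
  n <- length(dates)
  slot <- doy_slot(dates)
  base <- seasonal_sst_cycle(config, slot) +
    config$warming_trend * (seq_len(n) - 1L) / 3652.5

  resid <- with_scenario_seed(config$seed, {
    if (config$noise_sd == 0) {
      numeric(n)
    } else {
      e <- numeric(n)
      innov_sd <- config$noise_sd * sqrt(1 - config$ar1_coef^2)
      e[1L] <- stats::rnorm(1L, sd = config$noise_sd)
      z <- stats::rnorm(n - 1L, sd = innov_sd)
      for (t in 2:n) e[t] <- config$ar1_coef * e[t - 1L] + z[t - 1L]
      e
    }
  })
  v <- base + resid

  truth_rows <- lapply(config$injected_events, function(ev) {
    s <- ev$start_date
    e <- s + ev$duration - 1L
    if (s < dates[1L] || e > dates[n]) {
      stop(sprintf("invalid `injected_events`: episode %s..%s outside the %s..%s axis",
                   format(s), format(e), format(dates[1L]), format(dates[n])),
           call. = FALSE)
    }
    sel <- dates >= s & dates <= e
    sgn <- if (ev$polarity == "warm") 1 else -1
    v[sel] <<- v[sel] + sgn * ev$amplitude
    data.frame(polarity = ev$polarity, start = s, end = e,
               duration = ev$duration, amplitude = ev$amplitude,
               chla_response_sign = ev$chla_response_sign,
               chla_response_amp = ev$chla_response_amp,
               stringsAsFactors = FALSE)
  })
  events <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(polarity = character(), start = as.Date(character()),
               end = as.Date(character()), duration = integer(),
               amplitude = numeric(), chla_response_sign = integer(),
               chla_response_amp = numeric(), stringsAsFactors = FALSE)

  list(series = daily_series(dates, v, variable = "sst"),
       truth = structure(list(events = events,
                              axis = range(dates),
                              config = config),
                         class = "synthetic_truth"))
}

chla_mean_level <- function(config, dates) {
  slot <- doy_slot(dates)
  # circular distance to the bloom peak day
  d <- abs(slot - config$chla_bloom_peak_doy)
  d <- pmin(d, 365 - d)
  config$chla_base +
    config$chla_bloom_amp * exp(-0.5 * (d / config$chla_bloom_width_days)^2)
}

#' Generate a synthetic daily chlorophyll-a series
#'
#' Winter-bloom seasonal mean with multiplicative lognormal noise
#' (mean-corrected, so the expected value equals the mean level).  Each
#' injected SST episode with a nonzero response sign multiplies the mean
#' level by its `chla_response_amp` over the episode span shifted by
#' `coupling_lag_days`.  Missing days and optional > 10 mg/m3 outliers are
#' then injected.
#'
#' @param config the [scenario_config()] of the scenario.
#' @param sst_truth the `truth` component returned by [generate_sst()] for
#'   the same scenario.
#' @return A [daily_series()] of Chl-a (mg/m3) with attribute `chla_truth`
#'   (data frame of realized response spans and factors) and
#'   `outlier_dates` / `missing_dates` attributes.
#' @export
generate_chla <- function(config, sst_truth) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(sst_truth, "synthetic_truth"))
  dates <- scenario_dates(config)
  n <- length(dates)
  if (config$coupling_lag_days >= n) {
    stop("invalid `coupling_lag_days`: lag exceeds the series length",
         call. = FALSE)
  }
  mu <- chla_mean_level(config, dates)
  log_mu <- log(mu)

  ev <- sst_truth$events
  resp_rows <- list()
  if (nrow(ev) > 0L) {
    for (k in seq_len(nrow(ev))) {
      if (ev$chla_response_sign[k] == 0L) next
      s <- ev$start[k] + config$coupling_lag_days
      e <- ev$end[k] + config$coupling_lag_days
      sel <- dates >= s & dates <= e
      log_mu[sel] <- log_mu[sel] + log(ev$chla_response_amp[k])
      resp_rows[[length(resp_rows) + 1L]] <-
        data.frame(start = max(s, dates[1L]), end = min(e, dates[n]),
                   factor = ev$chla_response_amp[k],
                   sign = ev$chla_response_sign[k])
    }
  }

  out <- with_scenario_seed(config$seed + 1L, {
    sigma <- sqrt(log(1 + config$chla_noise_cv^2))
    v <- if (sigma == 0) exp(log_mu) else
      exp(log_mu + stats::rnorm(n, sd = sigma) - sigma^2 / 2)
    outlier <- if (config$outlier_rate > 0) {
      stats::runif(n) < config$outlier_rate
    } else rep(FALSE, n)
    v[outlier] <- stats::runif(sum(outlier), 10, 20)
    miss <- if (config$missing_fraction > 0) {
      stats::runif(n) < config$missing_fraction
    } else rep(FALSE, n)
    v[miss] <- NA_real_
    list(v = v, outlier = outlier, miss = miss)
  })

  s <- daily_series(dates, out$v, variable = "chla")
  attr(s, "chla_truth") <- if (length(resp_rows)) do.call(rbind, resp_rows) else
    data.frame(start = as.Date(character()), end = as.Date(character()),
               factor = numeric(), sign = integer())
  attr(s, "outlier_dates") <- dates[out$outlier]
  attr(s, "missing_dates") <- dates[out$miss]
  s
}

#' Generate an idealized temperature profile
#'
#' Isothermal at `surface_temp` down to the true mixed layer depth, then a
#' linear decrease at `thermocline_gradient`; an optional subsurface
#' intrusion adds a cool anomaly over a depth band (emulating an
#' intermediate-water layer).
#'
#' @param surface_temp mixed-layer temperature, degrees C.
#' @param mld_true true mixed layer depth, m; must lie within the depth span.
#' @param thermocline_gradient cooling rate below the mixed layer, degrees C
#'   per metre (>= 0).
#' @param depths strictly increasing depth grid, m, >= 2 levels.
#' @param date cast date.
#' @param intrusion optional `list(top =, bottom =, anomaly =)` subtracting
#'   `anomaly` degrees C between those depths.
#' @return A [temperature_profile()] with attribute `mld_true`.
#' @export
generate_profile <- function(surface_temp, mld_true, thermocline_gradient,
                             depths, date = as.Date("2010-11-15"),
                             intrusion = NULL) {
  depths <- as.numeric(depths)
  if (length(depths) < 2L || any(diff(depths) <= 0)) {
    stop("invalid `depths`: need >= 2 strictly increasing levels", call. = FALSE)
  }
  if (mld_true < depths[1L] || mld_true > depths[length(depths)]) {
    stop("invalid `mld_true`: outside the depth span", call. = FALSE)
  }
  if (thermocline_gradient < 0) {
    stop("invalid `thermocline_gradient`: must be >= 0", call. = FALSE)
  }
  temp <- ifelse(depths <= mld_true, surface_temp,
                 surface_temp - thermocline_gradient * (depths - mld_true))
  if (!is.null(intrusion)) {
    sel <- depths >= intrusion$top & depths <= intrusion$bottom
    temp[sel] <- temp[sel] - intrusion$anomaly
  }
  p <- temperature_profile(date, depths, temp)
  attr(p, "mld_true") <- mld_true
  p
}
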