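# Brute-force oracles: literal, loop-based implementations of the detection,
# matching and regression rules, kept independent of the package internals.

# day-by-day exceedance scan -> qualifying runs -> gap merge, all via loops
oracle_detect_spans <- function(values, thresholds, polarity,
                                min_duration, max_gap,
                                comparison = "strict") {
  n <- length(values)
  mask <- logical(n)
  for (i in seq_len(n)) {
    v <- values[i]; th <- thresholds[i]
    if (is.na(v)) { mask[i] <- FALSE; next }
    mask[i] <- if (polarity == "high") {
      if (comparison == "strict") v > th else v >= th
    } else {
      if (comparison == "strict") v < th else v <= th
    }
  }
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_duration) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  merged <- list(runs[[1L]])
  if (length(runs) > 1L) {
    for (k in 2:length(runs)) {
      last <- merged[[length(merged)]]
      if (runs[[k]][1L] - last[2L] - 1L <= max_gap) {
        merged[[length(merged)]] <- c(last[1L], runs[[k]][2L])
      } else {
        merged[[length(merged) + 1L]] <- runs[[k]]
      }
    }
  }
  data.frame(start = vapply(merged, `[`, integer(1), 1L),
             end = vapply(merged, `[`, integer(1), 2L))
}

# exhaustive pairwise matching check
oracle_match <- function(sst, chla, max_lag) {
  pairs <- list()
  for (i in seq_len(nrow(sst))) {
    for (j in seq_len(nrow(chla))) {
      overlap <- !(chla$start[j] > sst$end[i] || chla$end[j] < sst$start[i])
      gap <- as.integer(chla$start[j] - sst$end[i])
      if (overlap) {
        pairs[[length(pairs) + 1L]] <- c(i, j, "concurrent")
      } else if (gap >= 1L && gap <= max_lag) {
        pairs[[length(pairs) + 1L]] <- c(i, j, "lagged")
      }
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(sst_index = integer(), chla_index = integer(),
                      relation = character()))
  }
  data.frame(sst_index = as.integer(vapply(pairs, `[`, character(1), 1L)),
             chla_index = as.integer(vapply(pairs, `[`, character(1), 2L)),
             relation = vapply(pairs, `[`, character(1), 3L))
}

# closed-form OLS + t-test through stats::lm, the independent route
oracle_trend <- function(years, days) {
  fit <- stats::lm(days ~ years)
  sm <- summary(fit)
  list(slope_decade = 10 * unname(coef(fit)[2L]),
       p = sm$coefficients[2L, 4L],
       ci_decade = 10 * stats::confint(fit)[2L, ])
}

# a reusable seeded climatology holding all four working percentiles
make_test_clim <- function(seed = 42, n_years = 10, variable = "sst") {
  cfg <- scenario_config(n_years = n_years, start_year = 2000,
                         noise_sd = 0.5, ar1_coef = 0.5, seed = seed)
  s <- generate_sst(cfg)$series
  attr(s, "variable") <- variable
  build_climatology(s, percentiles = c(8, 10, 90, 92))
}

# random event tables on a date axis, for matching/classification tests
rand_event_table <- function(n, origin = as.Date("2005-01-01"),
                             span_days = 200, variable = "sst") {
  if (n == 0L) {
    return(data.frame(variable = character(), polarity = character(),
                      start = as.Date(character()), end = as.Date(character())))
  }
  start <- origin + sample.int(span_days, n, replace = TRUE) - 1L
  dur <- sample.int(15L, n, replace = TRUE)
  df <- data.frame(variable = variable,
                   polarity = sample(c("high", "low"), n, replace = TRUE),
                   start = start, end = start + dur - 1L)
  df[order(df$start), , drop = FALSE]
}

series_from_clim <- function(clim, dates, noise_sd = 0.5) {
  v <- clim$mean[doy_slot(dates)] + rnorm(length(dates), sd = noise_sd)
  daily_series(dates, v, variable = clim$variable)
}
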