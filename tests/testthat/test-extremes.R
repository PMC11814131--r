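test_that("printed-span durations follow the inclusive day-count convention", {
  expect_equal(duration_days(as.Date("2010-01-04"), as.Date("2010-03-19")), 75L)
  expect_equal(duration_days(as.Date("2006-12-14"), as.Date("2007-01-27")), 45L)
  expect_equal(duration_days(as.Date("2012-10-09"), as.Date("2012-10-27")), 19L)
  expect_equal(duration_days(as.Date("2010-11-07"), as.Date("2010-12-03")), 27L)
  expect_equal(duration_days(as.Date("2010-05-05"), as.Date("2010-05-05")), 1L)
  expect_error(duration_days(as.Date("2010-01-02"), as.Date("2010-01-01")),
               "precede")
})

test_that("runs below minimum duration are dropped, qualifying gaps merge", {
  cl <- make_test_clim(seed = 21)
  d <- seq(as.Date("2012-01-01"), as.Date("2012-12-31"), by = "day")
  slot <- doy_slot(d)
  base <- cl$mean[slot]

  # sitting on the climatological mean: no events of either polarity
  s0 <- daily_series(d, base, variable = "sst")
  expect_equal(nrow(detect_events(s0, cl, detection_params(90, 5, 2))), 0L)

  margin_hi <- cl$thresholds[slot, "p90"] - base + 0.5
  bump <- function(idx) {
    v <- base; v[idx] <- base[idx] + margin_hi[idx]
    daily_series(d, v, variable = "sst")
  }

  # 12 consecutive exceedant days, min 10 -> one event of duration 12
  ev <- detect_events(bump(101:112), cl, detection_params(90, 10, 0))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 12L)
  expect_equal(ev$polarity, "high")

  # 9 days -> nothing at min 10
  expect_equal(nrow(detect_events(bump(101:109), cl,
                                  detection_params(90, 10, 0))), 0L)

  # two 6-day runs split by a 2-day gap, min 5, max_gap 2 -> merged span of 14
  ev2 <- detect_events(bump(c(101:106, 109:114)), cl,
                       detection_params(90, 5, 2))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$start, d[101])
  expect_equal(ev2$end, d[114])
  expect_equal(ev2$duration, 14L)

  # with max_gap 1 the same input stays two events
  ev3 <- detect_events(bump(c(101:106, 109:114)), cl,
                       detection_params(90, 5, 1))
  expect_equal(nrow(ev3), 2L)

  # two 3-day runs with a 1-day gap never qualify at min 5 (filter first)
  ev4 <- detect_events(bump(c(101:103, 105:107)), cl,
                       detection_params(90, 5, 2))
  expect_equal(nrow(ev4), 0L)
})

test_that("event metrics equal a per-day brute-force loop", {
  cl <- make_test_clim(seed = 22)
  d <- seq(as.Date("2013-01-01"), as.Date("2013-12-31"), by = "day")
  set.seed(23)
  v <- cl$mean[doy_slot(d)] + rnorm(length(d))
  v[150] <- NA
  s <- daily_series(d, v, variable = "sst")

  span <- c(as.Date("2013-05-10"), as.Date("2013-06-20"))
  m <- event_metrics(s, cl, span, polarity = "high")

  idx <- which(d >= span[1] & d <= span[2])
  ints <- v[idx] - cl$mean[doy_slot(d[idx])]
  expect_equal(m$duration, length(idx))
  expect_equal(m$max_intensity, max(ints, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(m$mean_intensity, mean(ints, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(m$cumulative_intensity, sum(ints, na.rm = TRUE),
               tolerance = 1e-12)
  expect_equal(m$peak_date, d[idx][which.max(ints)])
  expect_equal(m$n_missing, 1L)

  # low polarity takes the most negative departure
  ml <- event_metrics(s, cl, span, polarity = "low")
  expect_equal(ml$max_intensity, min(ints, na.rm = TRUE), tolerance = 1e-12)

  # a single day at mean + 2.7 over a flat span peaks at 2.7
  v2 <- cl$mean[doy_slot(d)]
  v2[160] <- v2[160] + 2.7
  m2 <- event_metrics(daily_series(d, v2, variable = "sst"), cl,
                      c(d[150], d[170]), "high")
  expect_equal(m2$max_intensity, 2.7, tolerance = 1e-12)
  expect_equal(m2$peak_date, d[160])

  # span entirely at the mean: all intensities zero
  m3 <- event_metrics(daily_series(d, cl$mean[doy_slot(d)], variable = "sst"),
                      cl, c(d[10], d[20]), "high")
  expect_equal(m3$max_intensity, 0, tolerance = 1e-12)
  expect_equal(m3$cumulative_intensity, 0, tolerance = 1e-12)
})

test_that("detection equals the exhaustive scan on random series", {
  cl <- make_test_clim(seed = 31)
  params <- detection_params(90, 5, 2)
  d0 <- as.Date("2011-01-01")
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(60:400, 1)
    d <- seq(d0, by = "day", length.out = n)
    slot <- doy_slot(d)
    v <- cl$mean[slot] + rnorm(n, sd = 1.3)
    v[sample(n, n %/% 20)] <- NA
    s <- daily_series(d, v, variable = "sst")
    for (pol in c("high", "low")) {
      thr <- cl$thresholds[slot, if (pol == "high") "p90" else "p10"]
      want <- oracle_detect_spans(v, thr, pol, params$min_duration,
                                  params$max_gap)
      got <- detect_events(s, cl, params, polarity = pol)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want) > 0L) {
        expect_equal(got$start, d[want$start])
        expect_equal(got$end, d[want$end])
      }
    }
  }
})

test_that("low-event detection mirrors high-event detection", {
  cl <- make_test_clim(seed = 41)
  d <- seq(as.Date("2014-01-01"), by = "day", length.out = 400)
  slot <- doy_slot(d)
  set.seed(42)
  v <- cl$mean[slot] + rnorm(400, sd = 1.2)
  s <- daily_series(d, v, variable = "sst")

  # mirror the series and the thresholds about the climatological mean
  clm <- cl
  clm$thresholds[, "p10"] <- 2 * cl$mean - cl$thresholds[, "p90"]
  sm <- daily_series(d, 2 * cl$mean[slot] - v, variable = "sst")

  hi <- detect_events(s, cl, detection_params(90, 5, 2), polarity = "high")
  lo <- detect_events(sm, clm, detection_params(90, 5, 2), polarity = "low")
  expect_equal(lo$start, hi$start)
  expect_equal(lo$end, hi$end)
  expect_equal(lo$max_intensity, -hi$max_intensity, tolerance = 1e-12)
})

test_that("edge-truncated runs count and are flagged", {
  cl <- make_test_clim(seed = 51)
  d <- seq(as.Date("2012-03-01"), by = "day", length.out = 60)
  slot <- doy_slot(d)
  v <- cl$mean[slot]
  v[1:6] <- cl$thresholds[slot[1:6], "p90"] + 1   # run touching the start
  s <- daily_series(d, v, variable = "sst")
  ev <- detect_events(s, cl, detection_params(90, 5, 2), polarity = "high")
  expect_equal(nrow(ev), 1L)
  expect_true(ev$edge[1])
  expect_equal(ev$start, d[1])
})

test_that("variable mismatch and missing percentiles are errors", {
  cl <- make_test_clim(seed = 61)
  d <- seq(as.Date("2012-01-01"), by = "day", length.out = 100)
  s_chla <- daily_series(d, rep(1, 100), variable = "chla")
  expect_error(detect_events(s_chla, cl, params_chla()), "does not match")
  s <- daily_series(d, rep(20, 100), variable = "sst")
  cl95 <- cl; cl95$percentiles <- c(8, 10, 90, 92)
  expect_error(detect_events(s, cl, detection_params(95, 5, 2)),
               "95th percentile")
})
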