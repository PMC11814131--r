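events_df <- function(polarity, start, end, variable = "sst") {
  data.frame(variable = variable, polarity = polarity,
             start = as.Date(start), end = as.Date(end),
             stringsAsFactors = FALSE)
}

test_that("blooming windows resolve to the documented spans", {
  bp <- default_blooming_periods()
  expect_equal(resolve_period(bp$NRS, 2010),
               as.Date(c("2010-01-01", "2010-03-31")))
  expect_equal(resolve_period(bp$SRS, 2012),
               as.Date(c("2012-10-01", "2013-01-31")))
  expect_equal(resolve_period(bp$NCRS, 2005),
               as.Date(c("2005-12-01", "2006-02-28")))
  # leap year at the cross-year end
  expect_equal(resolve_period(bp$NCRS, 2007)[2], as.Date("2008-02-29"))
  expect_equal(resolve_period(bp$basin, 2000),
               as.Date(c("2000-10-01", "2001-03-31")))
  # single-month window covers the whole month
  expect_equal(resolve_period(blooming_period("X", 2, 2), 2016),
               as.Date(c("2016-02-01", "2016-02-29")))
})

test_that("concurrent and lagged matching follow the one-week rule", {
  sst <- events_df("high", "2010-01-10", "2010-01-20")
  chl <- events_df("low", "2010-01-15", "2010-01-18", "chla")
  m <- match_compounds(sst, chl, max_lag = 7)
  expect_equal(nrow(m), 1L)
  expect_equal(m$relation, "concurrent")
  expect_equal(m$direction, "expected")

  # start exactly 7 days after the SST end -> lagged; 8 days -> no match
  chl7 <- events_df("low", "2010-01-27", "2010-01-30", "chla")
  chl8 <- events_df("low", "2010-01-28", "2010-01-31", "chla")
  expect_equal(match_compounds(sst, chl7, 7)$relation, "lagged")
  expect_equal(nrow(match_compounds(sst, chl8, 7)), 0L)

  # same polarity pairs are flagged opposite
  chl_hi <- events_df("high", "2010-01-16", "2010-01-19", "chla")
  expect_equal(match_compounds(sst, chl_hi, 7)$direction, "opposite")
})

test_that("matching equals the exhaustive pairwise check on random sets", {
  set.seed(99)
  for (rep in 1:100) {
    sst <- rand_event_table(sample(0:6, 1))
    chl <- rand_event_table(sample(0:6, 1), variable = "chla")
    lag <- sample(3:10, 1)
    got <- match_compounds(sst, chl, max_lag = lag)
    want <- oracle_match(sst, chl, lag)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0L) {
      key <- function(df) paste(df$sst_index, df$chla_index, df$relation)
      expect_setequal(key(got), key(want))
    }
  }
})

test_that("blooming-period classification follows the precedence rules", {
  bp <- default_blooming_periods()$NRS

  # MHW with concurrent LChl-a -> expected
  c1 <- classify_blooming_period(bp, 2010,
    events_df("high", "2010-01-04", "2010-03-19"),
    events_df("low", "2010-02-09", "2010-02-26", "chla"))
  expect_equal(c1$classification, "expected")

  # MHW followed within the lag by HChl-a only -> opposite
  c2 <- classify_blooming_period(bp, 2010,
    events_df("high", "2010-01-10", "2010-01-25"),
    events_df("high", "2010-01-28", "2010-02-02", "chla"))
  expect_equal(c2$classification, "opposite")

  # MHW with no Chl-a extreme in the window -> sst_only
  c3 <- classify_blooming_period(bp, 2011,
    events_df("high", "2011-01-10", "2011-01-25"),
    events_df("low", "2011-06-01", "2011-06-05", "chla"))
  expect_equal(c3$classification, "sst_only")

  # no SST event in the window -> none, chl_only flagged
  c4 <- classify_blooming_period(bp, 2012,
    events_df("high", "2012-06-10", "2012-06-25"),
    events_df("high", "2012-02-01", "2012-02-06", "chla"))
  expect_equal(c4$classification, "none")
  expect_true(c4$chl_only)

  # both directions present -> expected with ambiguity flag
  c5 <- classify_blooming_period(bp, 2013,
    events_df("high", "2013-01-10", "2013-01-25"),
    events_df(c("low", "high"), c("2013-01-12", "2013-01-20"),
              c("2013-01-16", "2013-01-24"), "chla"))
  expect_equal(c5$classification, "expected")
  expect_true(c5$ambiguous)
})

test_that("window clipping is by calendar-day intersection", {
  bp <- default_blooming_periods()$NRS
  # event overlapping the boundary by one day is in; fully outside is not
  cin <- classify_blooming_period(bp, 2010,
    events_df("high", "2009-12-20", "2010-01-01"),
    events_df("low", "2010-01-02", "2010-01-06", "chla"))
  expect_equal(nrow(cin$sst_events), 1L)
  cout <- classify_blooming_period(bp, 2010,
    events_df("high", "2009-12-20", "2009-12-31"),
    events_df("low", "2010-01-02", "2010-01-06", "chla"))
  expect_equal(cout$classification, "none")
})

test_that("classification is invariant to event order", {
  bp <- default_blooming_periods()$SRS
  sst <- events_df(c("high", "low"), c("2012-10-05", "2012-12-01"),
                   c("2012-10-20", "2012-12-15"))
  chl <- events_df(c("high", "low"), c("2012-12-03", "2012-10-07"),
                   c("2012-12-08", "2012-10-10"), "chla")
  ref <- classify_blooming_period(bp, 2012, sst, chl)$classification
  for (i in 1:5) {
    p1 <- sample(nrow(sst)); p2 <- sample(nrow(chl))
    expect_equal(classify_blooming_period(bp, 2012, sst[p1, ], chl[p2, ])$classification,
                 ref)
  }
})

test_that("case summaries tally classifications correctly", {
  bp <- default_blooming_periods()$NRS
  mk <- function(year, kind) {
    sst <- events_df("high", sprintf("%d-01-10", year), sprintf("%d-01-25", year))
    chl <- switch(kind,
      expected = events_df("low", sprintf("%d-01-12", year),
                           sprintf("%d-01-20", year), "chla"),
      sst_only = events_df("low", sprintf("%d-07-01", year),
                           sprintf("%d-07-05", year), "chla"))
    classify_blooming_period(bp, year, sst, chl)
  }
  cases <- c(lapply(2000:2014, mk, kind = "expected"),
             list(mk(2015, "sst_only")))
  sm <- summarize_cases(cases)
  expect_equal(sm$n_cases, 16L)
  expect_equal(unname(sm$counts["expected"]), 15L)
  expect_equal(unname(sm$counts["sst_only"]), 1L)
  expect_equal(sm$percent_expected, 93.75)
  expect_equal(sm$percent_expected_rounded, 94)
  expect_equal(sum(sm$counts), length(cases))

  # zero expected
  sm0 <- summarize_cases(list(mk(2000, "sst_only"), mk(2001, "sst_only")))
  expect_equal(sm0$percent_expected, 0)
  expect_error(summarize_cases(list()), "no cases")

  # randomized sets equal a hand tally
  set.seed(123)
  for (rep in 1:20) {
    kinds <- sample(c("expected", "sst_only"), 10, replace = TRUE)
    cs <- mapply(mk, 2000:2009, kinds, SIMPLIFY = FALSE)
    sm2 <- summarize_cases(cs)
    expect_equal(sm2$percent_expected,
                 100 * sum(kinds == "expected") / length(kinds))
  }
})
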