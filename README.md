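# mhwcompound

Detection and analysis of **compound SST–chlorophyll extreme events** in
daily ocean time series.

In nutrient-limited seas the winter phytoplankton bloom depends on
convective mixing.  Marine heatwaves (MHWs) stratify the upper ocean and
suppress the bloom; marine cold-spells (MCSs) deepen the mixed layer and
fertilize it.  `mhwcompound` implements the full chain needed to test this
expected response pattern:

* **Percentile climatologies** — day-of-year baselines built by pooling an
  11-day window across reference years, with percentile thresholds
  (90th/10th, 92nd/8th, ...), moving-mean smoothing, and standardized
  anomalies ((x − clim)/sd).
* **Event detection** — exceedance runs against the daily threshold with a
  minimum duration (5 d trend-mode SST, 10 d compound-mode SST, 3 d Chl-a)
  and gap joining (≤ 2 d for SST), plus per-event max/mean/cumulative
  intensity relative to the climatological mean.
* **Compound matching** — SST and Chl-a extremes pair when their spans
  overlap, or when the Chl-a extreme starts within 7 days of the SST event
  end; each regional blooming period (e.g. Jan–Mar north, Oct–Jan south) is
  classified `expected` / `opposite` / `sst_only` / `none`.
* **Decadal trends** — OLS slope of seasonal event days in days/decade with
  a two-sided t-test, per series or per grid pixel.
* **Mixed layer depth** — the 0.2 °C temperature-difference criterion
  against the 10 m reference, with interpolation between levels and daily
  anomaly computation.
* **Synthetic scenarios** — seasonal cycle + AR(1) noise + warming trend
  SST, lognormal winter-bloom Chl-a with missing days and QC-triggering
  outliers, injected warm/cold episodes with lagged, sign-opposed Chl-a
  responses, and idealized temperature profiles — all with recorded ground
  truth, so every stage is testable without external data.

## Worked example

Inject a 75-day warm episode and a 45-day cold episode into a 21-year
synthetic scenario, then detect them in compound mode (92nd/8th percentile,
≥ 10 days):

```r
library(mhwcompound)

ev  <- list(injected_event("warm", "2010-01-04", 75, 2.0),
            injected_event("cold", "2006-12-14", 45, 1.8))
cfg <- scenario_config(n_years = 21, start_year = 1998, seed = 7,
                       injected_events = ev)
sst  <- generate_sst(cfg)
chla <- interpolate_gaps(generate_chla(cfg, sst$truth))

clim_sst  <- build_climatology(sst$series, percentiles = c(8, 10, 90, 92))
clim_chla <- build_climatology(chla, percentiles = c(10, 90))

events_sst  <- detect_events(sst$series, clim_sst, params_sst_compound())
events_chla <- detect_events(chla, clim_chla, params_chla())
subset(events_sst, duration >= 40,
       select = c(polarity, start, end, duration, max_intensity))
#>  polarity      start        end duration max_intensity
#>       low 2006-12-14 2007-01-27       45     -2.345230
#>      high 2010-01-04 2010-03-19       75      2.688267
```

Both injected episodes are recovered with exact boundaries: a 45-day
cold-spell peaking 2.3 °C below the climatological mean and a 75-day
heatwave peaking 2.7 °C above it.  Classify the 2010 January–March blooming
period and fit a decadal trend of trend-mode MHW days over the Oct–Mar
growth season:

```r
nrs <- default_blooming_periods()$NRS
classify_blooming_period(nrs, 2010, events_sst, events_chla)$classification
#> [1] "expected"     # the MHW paired with a low-Chl-a extreme

tr_events <- detect_events(sst$series, clim_sst, params_sst_trend())
basin <- default_blooming_periods()$basin
days <- sapply(1998:2017, function(y)
  seasonal_event_days(tr_events[tr_events$polarity == "high", ], basin, y))
decadal_trend(data.frame(season_year = 1998:2017, days = days))
#> <trend: +0.83 days/decade (se 6.63), p = 0.902, n = 20>
```

With no injected warming trend the estimated slope is indistinguishable
from zero, as it should be.  `run_pipeline()` executes the whole chain
(simulate → climatology → detect → compound → trend → MLD) and writes CSV
artifacts; `inst/scripts/mhw-pipeline.R` is a thin command-line wrapper.

See `vignettes/compound-extremes.Rmd` for the model, parameter and design
documentation.

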