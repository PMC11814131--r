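---
title: "Detecting compound SST-chlorophyll extremes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting compound SST-chlorophyll extremes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhwcompound)
```

## The problem

In tropical and subtropical seas, winter phytoplankton blooms depend on
convective mixing that lifts nutrients into the euphotic zone.  Marine
heatwaves (MHWs) — prolonged periods of anomalously warm surface water —
are associated with a shallower mixed layer, stronger stratification and
suppressed nutrient supply, and hence with *low* chlorophyll-a (Chl-a)
extremes during the blooming season.  Marine cold-spells (MCSs) act in the
opposite direction: deeper mixing, higher nutrient flux, *high* Chl-a
extremes.  `mhwcompound` implements the full analysis chain for testing this
expected response pattern on daily time series: percentile-climatology
construction, run-length event detection for both SST and Chl-a, compound
matching inside regional blooming windows, decadal trends of event days, and
a temperature-criterion mixed layer depth (MLD) diagnostic, together with a
ground-truthed synthetic scenario generator.

## Event definition

A day is *exceedant* when its value crosses the day-of-year percentile
threshold: above the upper percentile for MHW / high-Chl-a detection, below
the lower percentile (100 − upper) for MCS / low-Chl-a.  Maximal exceedance
runs of at least `min_duration` days become candidate events; candidates
separated by at most `max_gap` non-exceedant days are merged (filter first,
then merge, so gap days never help a short run qualify).  Defaults:

| use                | percentiles | min_duration | max_gap |
|--------------------|------------:|-------------:|--------:|
| SST, trend mode    | 90 / 10     | 5 d          | 2 d     |
| SST, compound mode | 92 / 8      | 10 d         | 2 d     |
| Chl-a              | 90 / 10     | 3 d          | 0 d     |

Gap joining follows the established MHW-toolbox convention of bridging up to
2 non-exceedant days.  For Chl-a we disable it: with a 3-day minimum
duration, 2-day joins would let merge artifacts dominate the catalog.  The
threshold comparison is strict (`>` / `<`) by default; both choices are
configurable in `detection_params()`.  Missing days are never exceedant, so
they break SST runs; Chl-a detection is meant to run on the
gap-interpolated series produced by preprocessing (`interpolate_gaps()` /
`preprocess_chla()`).  Runs truncated by the series boundary count if their
observed length qualifies, and are flagged `edge`.

Per-event intensity is the departure from the climatological *mean* (not
the threshold): `max_intensity` is the signed extreme over the span,
`mean_intensity` and `cumulative_intensity` aggregate all non-missing span
days, merged-gap days included.

## Climatology construction

For each of 365 calendar-day slots, all non-missing values whose slot lies
within ±5 days (circularly across the year boundary) are pooled across every
reference year; slot mean, standard deviation and the requested percentiles
are computed on the pool, and each statistic is smoothed by a centred
circular moving mean.  Numerical choices:

* **Smoothing width.** The conventional "30-day moving mean" is ambiguous
  for a centred window; we use a 31-day centred window by default
  (`smooth_window`, configurable and recorded on the object).
* **Percentile rule.** Linear interpolation between order statistics
  (`stats::quantile` type 7), configurable via `percentile_type` because
  threshold values are sensitive to it.
* **Leap days.** A 365-slot climatology; 29 February contributes to and
  reads from the 28 February slot — the standard convention in the MHW
  software ecosystem.
* **Missing data** are dropped from pools, never imputed; a slot errors
  only if its pool is entirely empty.
* **Reference period** is always an explicit argument: a long baseline for
  trend analysis and a shorter one matching ocean-colour availability for
  compound analysis are both first-class.
* The standard deviation used for standardized anomalies
  (`standardized_anomaly()`) goes through the same pool-and-smooth pipeline
  as the mean; whether to smooth it is genuinely open, and we chose
  consistency with the mean.

## Compound matching and classification

Blooming windows are month/day windows per region, possibly crossing the
year boundary (resolved into `season_year`..`season_year + 1`); the
built-ins are northern Jan–Mar, north-central and south-central Dec–Feb,
southern Oct–Jan and basin-wide Oct–Mar.  A SST event and a Chl-a event
match *concurrent* when their spans share a calendar day, and *lagged* when
the Chl-a event starts 1..7 days (configurable `max_lag`) after the SST
event's **end** — "following within a week" is anchored on the event end,
a documented reading since the anchor is genuinely ambiguous.

Each blooming period is one case.  Events are clipped to the window by
any-day overlap (metrics are not re-clipped).  Classification precedence is
deterministic: `expected` (≥ 1 MHW–LChl-a or MCS–HChl-a match) >
`opposite` (matches exist, wrong direction only) > `sst_only` (SST extremes,
no matched Chl-a extreme) > `none`.  A case with matches in both directions
classifies `expected` with an `ambiguous` flag.  Periods with Chl-a extremes
but no SST event are flagged `chl_only` and excluded from the
percent-expected denominator.

## Trends

`seasonal_event_days()` counts event days inside the resolved window
(overlap days only).  `decadal_trend()` is closed-form ordinary least
squares of annual day counts on season year; the slope is reported per
decade (10 × per-year) with a two-sided t-test on n − 2 degrees of freedom.
Constant series (zero residual variance, zero slope) report slope 0 and
p = 1 with a `degenerate` flag instead of erroring, so flat map pixels
survive `trend_map()`.  No autocorrelation correction is applied to the
t-test — a known limitation, consistent with common practice in the MHW
trend literature.  Cross-year seasons are labelled by their starting year.

## Mixed layer depth

`compute_mld()` implements the temperature-difference criterion: reference
temperature linearly interpolated at 10 m, MLD at the shallowest depth below
where the temperature deficit reaches 0.2 °C, localized by linear
interpolation between bracketing levels (a midpoint rule was rejected as
grid-dependent).  Profiles that never reach the deficit return the deepest
level flagged `bottom_reached`; casts starting more than 5 m below the
reference depth return `no_surface_level`.  Depth is positive downward;
pressure-to-depth conversion is the caller's responsibility.  The criterion
uses temperature only; salinity is carried but unused.  MLD anomalies are
positive-deeper, with the sign convention recorded on the output.

## The synthetic generator

`scenario_config()` / `generate_sst()` / `generate_chla()` /
`generate_profile()` emulate the statistical structure of spatially
averaged daily satellite SST and ocean-colour series and of float
temperature profiles:

* SST = seasonal cosine (late-summer peak) + linear warming trend + AR(1)
  Gaussian residuals with marginal sd `noise_sd`; injected episodes add
  ±`amplitude` over exact spans, recorded as ground truth.
* Chl-a = winter-bloom Gaussian bump in the seasonal mean with
  multiplicative lognormal noise (mean-corrected, so the expected value
  equals the mean level — Chl-a is positive and right-skewed); episode
  responses multiply the mean level (additive in log space) over the
  lagged span, so expected responses are analytically checkable; missing
  days and rare > 10 mg/m³ spikes exercise the quality-control path.
* Profiles are isothermal to the true MLD, then linear cooling, with an
  optional cool subsurface intrusion band.

The upstream data products' distributions are not documented, so all noise
choices are stand-ins chosen for realism (positive skew for Chl-a,
persistence for SST), not estimates fitted to any dataset.  The generator
does **not** emulate spatially correlated noise fields, physically coupled
MLD–SST dynamics, sensor drift, or cloud-correlated missingness — passing
tests demonstrate the correctness of the detection chain, not product-level
fidelity.

### Validation conditions

The test suite validates recovery under fixed conditions chosen once:

* **Null calibration** uses a 20-year, `ar1 = 0.7`, `noise_sd = 0.4 °C`
  scenario; about 10% of days fall above the 90th-percentile threshold by
  construction, permissive-rule MHWs are rare but nonzero, and the strict
  compound rule yields strictly fewer events.
* **Boundary recovery** injects 10-day episodes of 2.5 °C — the magnitude
  of the strongest documented case-study events, several times the local
  threshold margin — into a 21-year baseline, so the episode does not
  contaminate its own climatology pools.  Residuals here are weakly
  autocorrelated (`ar1 = 0.2`): with persistence-dominated noise the days
  adjacent to an episode are frequently *genuinely* extreme, and a
  ±1-day boundary target is not an identifiable property of the detector.
  With realistic persistence the same detector recovers the episodes but
  the detected spans extend past the injected boundaries a few percent of
  the time, for that reason.
* **Compound recovery** keeps realistic persistence (`ar1 = 0.6`) and a
  strong coupled response (× 0.4 suppression or × 2.5 elevation, 3-day
  lag) and checks end-to-end expected-direction classification.

Problem sizes (5–21 simulated years, 100–1000 replicates for oracle and
recovery suites) were chosen so the whole suite runs in a few minutes on a
single core while keeping binomial noise on rate estimates near or below
one percentage point.

## Quality control and regional configuration

`preprocess_chla()` masks pixels above 10 mg/m³ (false extremes for
oligotrophic basins), drops days with valid-pixel coverage below 30%
("less than 30% removed" reads as *keep exactly 30.0%*), spatially averages
the rest, and linearly interpolates interior gaps of the resulting series
(leading/trailing gaps stay missing).  Spatial means are unweighted by
default with optional cos(latitude) weighting — a second-order choice at
the latitude spans involved.  Region boundaries are mandatory configuration
inputs; the shipped `regions_example.yml` is illustrative only.  Gridded
I/O is CSV/in-memory; the gridded containers are plain arrays with
coordinate vectors.

## Known limitations

* The t-test on trends ignores serial correlation of annual counts.
* Detection operates on one series at a time; `trend_map()` loops pixels
  rather than vectorizing across space.
* The synthetic Chl-a missingness is independent Bernoulli, unlike real
  cloud-driven gaps which are strongly clustered; interpolation error under
  clustered gaps is therefore not exercised.
* Event categories (moderate/strong/severe) and detrended-baseline variants
  are out of scope.
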