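Package: mhwcompound
Title: Marine Heatwave, Cold-Spell and Chlorophyll-a Extreme Detection
    with Compound-Event Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects marine heatwaves (MHWs), marine cold-spells (MCSs)
    and high/low chlorophyll-a extremes from daily time series using
    day-of-year percentile climatologies (windowed pooling with moving-mean
    smoothing), run-length event detection with minimum duration and gap
    joining, and per-event intensity metrics.  Matches SST and
    chlorophyll-a extremes into compound events within regional
    phytoplankton blooming periods and classifies each period against the
    expected stratification/mixing response pattern.  Quantifies decadal
    trends in extreme-event days by ordinary least squares with two-sided
    t-tests, estimates mixed layer depth from discrete temperature
    profiles by a temperature-difference criterion, and ships a synthetic
    scenario generator (seasonal cycles, AR(1) noise, warming trends,
    injected coupled episodes) so the whole pipeline is testable without
    external satellite or float data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
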