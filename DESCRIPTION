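Package: templag
Title: Distributed-Lag Nonlinear Case-Crossover Analysis of Temperature and
    Daily Event Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating nonlinear and delayed associations between
    daily mean temperature and daily event counts (such as road-traffic
    fatalities) with a time-stratified case-crossover design. Implements
    natural cubic spline cross-bases over exposure and lag, a conditional
    Poisson fitter that profiles out year-by-month-by-weekday stratum
    intercepts, minimum-mortality temperature estimation, single-lag and
    cumulative odds-ratio tables at extreme temperature percentiles, a
    sensitivity-analysis grid over lag windows, confounder flexibility and
    percentile thresholds, and a synthetic daily-series generator with
    closed-form true effect surfaces for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
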