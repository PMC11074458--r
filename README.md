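# templag

Distributed-lag nonlinear case-crossover analysis of daily mean temperature
and daily event counts, built for the road-traffic-fatality setting: how do
cold and hot days change the risk of dying on the road, today and over the
following two weeks?

`templag` is aimed at environmental epidemiologists who have (or want to
simulate) a daily city-level series — death counts by transport mode, daily
mean temperature, relative humidity, barometric pressure, wind speed and
routine pollutant concentrations — and want the standard analysis of that
design end to end:

* **time-stratified case-crossover strata**: each day is self-matched to
  the other days of the same year x month x day-of-week cell (4–5 days per
  stratum, so up to 4 referent days per case);
* **a natural cubic spline cross-basis** over exposure and lag
  (defaults: lag window 0–14 days, 2 df in each dimension), giving the
  distributed-lag nonlinear surface
  `log OR(x, l) = sum_jk beta_jk Bx_j(x) Bl_k(l)`;
* **conditional Poisson regression** with the hundreds of stratum
  intercepts profiled out in closed form (verified against the equivalent
  dummy-variable GLM to < 1e-6), adjusting for humidity (3-df spline) and
  for each pollutant that passes a |Spearman r| < 0.6 collinearity screen
  against temperature (2-df splines);
* **reportables**: the minimum-mortality temperature (MMT) from the
  cumulative exposure–response curve, extreme-temperature thresholds
  (1st/99th percentiles by default), and single-lag plus cumulative
  "Lag0–h" odds-ratio tables with delta-method 95% CIs, all referenced to
  the fitted MMT;
* **a sensitivity grid** over lag windows {7, 14, 21} x humidity df
  {2, 3, 4} x percentile pairs {(1,99), (2.5,97.5), (10,90)};
* **a synthetic daily-series generator** with closed-form truth surfaces
  (null / linear / U-shaped), calibrated to published marginal summaries of
  a 10-year temperate-monsoon registry series, for coverage and recovery
  studies when no real registry series is available.

## A worked example

```r
library(templag)

sim <- simulate_daily_series(sim_config(truth = truth_surface("u-shaped"),
                                        random_seed = 7))
report <- run_analysis(sim$series, analysis_config(subgroups = "total"))
report
#> Case-crossover DLNM run over 3653 days
#>   extreme thresholds: -4.4 / 34.9 degrees C
#>   total         MMT   14.4 C; cumulative OR(lag 0-14) low 1.822, high 2.032
```

Ten simulated years (3,653 days) under a known U-shaped truth surface: the
1st/99th-percentile thresholds of the simulated temperatures are −4.4 °C
and 34.9 °C, the fitted cumulative exposure–response curve reaches its
minimum (the MMT, the reference for all odds ratios) at 14.4 °C, and the
risk cumulated over lags 0–14 is elevated at both extremes. The full table
behind those two headline numbers:

```r
subset(report$models$total$effects, type == "cumulative" & lag %in% c(7, 14))
#>          type      temp lag     logor         se       or       lo       hi
#> 16 cumulative -4.400203   7 0.4526591 0.07688365 1.572488 1.352521 1.828230
#> 30 cumulative -4.400203  14 0.5999534 0.10486527 1.822034 1.483525 2.237783
#> 46 cumulative 34.869928   7 0.5263454 0.08993901 1.692735 1.419164 2.019041
#> 60 cumulative 34.869928  14 0.7087978 0.12598219 2.031547 1.587050 2.600538
```

Because the series is synthetic the right answer is known in closed form:

```r
true_cumulative_or(sim$truth, unname(report$thresholds["high"]), horizon = 14)
#> [1] 1.647307
```

The single-replicate estimate (OR 2.03, 95% CI 1.59–2.60) covers that
truth; the test suite runs 200 such replicates and checks that coverage is
nominal and bias negligible. `run_sensitivity()` produces the 27-cell
robustness grid, and `write_run_report()` / `run_analysis(..., out_dir=)`
emit all tables as delimited text with a JSON provenance manifest.

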