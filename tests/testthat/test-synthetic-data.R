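test_that("the generator is deterministic given its configuration", {
  a <- quick_sim(years = 1, seed = 77)
  b <- quick_sim(years = 1, seed = 77)
  expect_identical(a$series, b$series)
  c2 <- quick_sim(years = 1, seed = 78)
  expect_false(identical(a$series$deaths_total, c2$series$deaths_total))
})

test_that("null-truth series matches its configured marginals", {
  sim <- simulate_daily_series(sim_config(
    start_date = "2011-01-01", end_date = "2020-12-31",
    truth = truth_surface("null"), random_seed = 101))
  s <- sim$series
  expect_equal(nrow(s), 3653)                      # 10 calendar years
  expect_lt(abs(mean(s$deaths_total) - 3), 0.2)    # baseline 3 deaths/day
  expect_lt(abs(mean(s$temp_mean_c) - 15.1), 0.5)
  # decade extremes bracket roughly -12 and 34 degrees C; the symmetric
  # noise model spreads the upper tail wider than the real (left-skewed)
  # series, so the brackets are generous on the high side
  expect_lt(min(s$temp_mean_c), -6)
  expect_gt(min(s$temp_mean_c), -24)
  expect_gt(max(s$temp_mean_c), 30)
  expect_lt(max(s$temp_mean_c), 46)
  expect_lt(abs(mean(s$rh_pct) - 55), 3)
})

test_that("subgroup counts always sum to the daily total", {
  sim <- quick_sim(years = 2, seed = 5)
  s <- sim$series
  parts <- s$deaths_walking + s$deaths_bicycle + s$deaths_motorcycle +
    s$deaths_motorvehicle + s$deaths_other
  expect_identical(parts, s$deaths_total)
  shares <- colSums(s[paste0("deaths_", c("walking", "bicycle", "motorcycle",
                                          "motorvehicle", "other"))]) /
    sum(s$deaths_total)
  expect_lt(max(abs(shares - c(0.459, 0.1505, 0.1689, 0.1624, 0.0592))), 0.03)
})

test_that("true cumulative OR identities hold", {
  nul <- truth_surface("null")
  expect_identical(true_cumulative_or(nul, 30, horizon = 14), 1)
  expect_identical(true_cumulative_or(nul, -5, horizon = 3), 1)

  lin <- truth_surface("linear-lag-decay", slope = 0.01, ref = 15)
  expect_equal(true_cumulative_or(lin, 15, horizon = 7), 1)
  # brute-force summation oracle over the lag window
  for (x in c(-6, 25, 32)) for (h in c(0, 5, 14)) {
    brute <- exp(sum(vapply(0:h, function(l)
      0.01 * (x - 15) * (1 - l / 15), numeric(1))))
    expect_equal(true_cumulative_or(lin, x, horizon = h), brute,
                 tolerance = 1e-12)
  }
  expect_error(true_cumulative_or(lin, 20, horizon = 15), "horizon")
})

test_that("the u-shaped surface is centred at its reference and convex-like", {
  tr <- truth_surface("u-shaped")
  expect_equal(truth_logor(tr, tr$ref, 0:14), rep(0, 15))
  grid <- seq(-13, 35, length.out = 200)
  f0 <- truth_logor(tr, grid, 0)
  expect_true(all(f0 >= -1e-12))                   # minimum is zero
  expect_gt(f0[1], 0.01)                           # risk rises at both ends
  expect_gt(f0[200], 0.01)
  # lag weights decay linearly to zero past the window
  expect_equal(truth_logor(tr, 30, 0) * (1 - 14 / 15), truth_logor(tr, 30, 14))
})

test_that("configuration contracts are enforced", {
  expect_error(sim_config(start_date = "2020-01-01", end_date = "2019-01-01"),
               "after")
  expect_error(sim_config(temp_ar1_coefficient = 1.2), "-1, 1")
  expect_error(sim_config(baseline_daily_mean_deaths = 0), "positive")
  expect_error(sim_config(subgroup_shares = c(a = 0.5, b = 0.4)), "sum to 1")
})

test_that("negative-binomial switch produces overdispersed counts", {
  po <- quick_sim(years = 3, seed = 8)
  nb <- quick_sim(years = 3, seed = 8, nb_size = 1)
  expect_gt(var(nb$series$deaths_total), 2 * var(po$series$deaths_total))
})

test_that("series round-trips through the delimited format with sidecar", {
  sim <- quick_sim(years = 1, truth = truth_surface("u-shaped"), seed = 3)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(path, paste0(path, ".truth.json"))), add = TRUE)
  write_daily_series(sim, path)
  expect_true(file.exists(paste0(path, ".truth.json")))
  side <- jsonlite::read_json(paste0(path, ".truth.json"))
  expect_equal(side$form, "u-shaped")
  expect_equal(side$random_seed, 3)
  back <- read_daily_series(path)
  expect_equal(back$date, sim$series$date)
  expect_equal(back$deaths_total, sim$series$deaths_total)
  expect_equal(back$temp_mean_c, sim$series$temp_mean_c, tolerance = 1e-12)
})
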