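test_that("the reference temperature is its own exact null", {
  tf <- toy_fit(n = 400, seed = 21)
  ref <- median(tf$x)
  for (l in c(0, 2, 5)) {
    est <- single_lag_or(tf$fit, tf$spec, ref, ref, l)
    expect_identical(est$or, 1)
    expect_identical(c(est$lo, est$hi), c(1, 1))
    expect_identical(est$se, 0)
  }
  cum <- cumulative_or(tf$fit, tf$spec, ref, ref, 5)
  expect_identical(cum$or, 1)
})

test_that("cumulative log-OR is exactly the sum of single-lag log-ORs", {
  tf <- toy_fit(n = 400, seed = 22, beta_signal = 0.15)
  ref <- median(tf$x)
  x <- unname(quantile(tf$x, 0.99))
  for (h in 0:tf$spec$max_lag) {
    singles <- vapply(0:h, function(l)
      single_lag_or(tf$fit, tf$spec, x, ref, l)$logor, numeric(1))
    cum <- cumulative_or(tf$fit, tf$spec, x, ref, h)
    expect_equal(cum$logor, sum(singles), tolerance = 1e-12)
  }
  expect_equal(cumulative_or(tf$fit, tf$spec, x, ref, 0),
               single_lag_or(tf$fit, tf$spec, x, ref, 0))
})

test_that("a linear exposure basis scales contrasts linearly", {
  tf <- toy_fit(n = 400, seed = 23, df_x = 1)
  ref <- 12
  for (l in 0:3) {
    a <- single_lag_or(tf$fit, tf$spec, ref + 2, ref, l)$logor
    b <- single_lag_or(tf$fit, tf$spec, ref + 4, ref, l)$logor
    expect_equal(b, 2 * a, tolerance = 1e-10)
  }
})

test_that("delta-method CIs agree with a parametric bootstrap", {
  tf <- toy_fit(n = 500, seed = 24, beta_signal = 0.1)
  ref <- median(tf$x)
  x <- unname(quantile(tf$x, 0.95))
  est <- cumulative_or(tf$fit, tf$spec, x, ref, tf$spec$max_lag)
  set.seed(99)
  ndraw <- 4000
  ch <- chol(tf$fit$vcov)
  draws <- matrix(rnorm(ndraw * length(tf$fit$coef)), ndraw) %*% ch
  draws <- sweep(draws, 2, tf$fit$coef, "+")
  v <- numeric(length(tf$fit$coef))
  names(v) <- names(tf$fit$coef)
  v[tf$fit$cb_cols] <- templag:::.cb_contrast(tf$spec, x, ref, 0:tf$spec$max_lag)
  boot_logor <- drop(draws %*% v)
  expect_lt(abs(sd(boot_logor) - est$se) / est$se, 0.05)
  expect_lt(abs(mean(boot_logor) - est$logor), 3 * est$se / sqrt(ndraw))
})

test_that("MMT of a strictly increasing curve is the lowest temperature", {
  x <- seq(-10, 30, length.out = 200)
  spec <- default_crossbasis_spec(x, max_lag = 4, df_x = 1, df_l = 2)
  # choose coefficients so the cumulative curve strictly increases in x
  u <- colSums(ns_basis(spec$lag, 0:4))
  up <- sign(diff(ns_basis(spec$exposure, c(-10, 30))[, 1]))
  fit <- fake_fit(up * u, spec)
  mmt <- find_mmt(fit, spec)
  expect_equal(as.numeric(mmt), min(x), tolerance = 1e-9)
})

test_that("a flat (null) curve ties to the lowest grid temperature", {
  x <- seq(-10, 30, length.out = 200)
  spec <- default_crossbasis_spec(x, max_lag = 4, df_x = 2, df_l = 2)
  fit <- fake_fit(rep(0, 4), spec)
  expect_equal(as.numeric(find_mmt(fit, spec)), min(x), tolerance = 1e-9)
})

test_that("MMT recovers the minimum of a U-shaped truth", {
  # large counts shrink estimation noise so the curve minimum is sharp
  tr <- truth_surface("u-shaped")
  sim <- quick_sim(years = 6, truth = tr, seed = 31,
                   baseline_daily_mean_deaths = 200)
  s <- sim$series
  spec <- default_crossbasis_spec(s$temp_mean_c, 14, 2, 2)
  fit <- fit_conditional_poisson(build_crossbasis(s$temp_mean_c, spec),
                                 build_confounder_design(s),
                                 s$deaths_total, assign_strata(s$date))
  mmt <- find_mmt(fit, spec)
  expect_lt(abs(as.numeric(mmt) - tr$ref), 1.5)
})

test_that("extreme thresholds are type-7 percentiles", {
  expect_equal(unname(extreme_thresholds(0:100)), c(1, 99))
  expect_equal(unname(extreme_thresholds(c(1, 2, 3, 4, 100), 50, 99))[1], 3)
  expect_equal(unname(extreme_thresholds(0:100, 2.5, 97.5)), c(2.5, 97.5))
  expect_equal(unname(extreme_thresholds(0:100, 10, 90)), c(10, 90))
  expect_error(extreme_thresholds(numeric(0)), "empty")
  expect_error(extreme_thresholds(0:100, 99, 1), "p_low")
})

test_that("evaluation outside the observed range is refused by default", {
  tf <- toy_fit(n = 300, seed = 25)
  hi <- max(tf$x) + 5
  expect_error(cumulative_or(tf$fit, tf$spec, hi, median(tf$x), 3),
               "outside the observed range")
  est <- cumulative_or(tf$fit, tf$spec, hi, median(tf$x), 3,
                       allow_extrapolation = TRUE)
  expect_true(is.finite(est$or))
})

test_that("OR always lies inside its CI and all are positive", {
  tf <- toy_fit(n = 400, seed = 26, beta_signal = 0.2)
  eff <- effect_table(tf$fit, tf$spec,
                      unname(quantile(tf$x, c(0.01, 0.99))), median(tf$x))
  expect_true(all(eff$lo <= eff$or + 1e-12 & eff$or <= eff$hi + 1e-12))
  expect_true(all(eff$lo > 0))
  expect_equal(eff$or, exp(eff$logor))
})
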