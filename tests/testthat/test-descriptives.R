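test_that("percentage shares reproduce the published-table arithmetic", {
  counts <- jinan_published_counts()
  sex <- counts$total[counts$dimension == "sex"]
  expect_equal(sum(sex), 9794L)
  expect_equal(percent_share(sex), c(73.01, 26.99))
  mode <- counts$total[counts$dimension == "transport"]
  expect_equal(sum(mode), 9794L)
  expect_equal(percent_share(mode), c(45.90, 15.05, 16.89, 16.24, 5.92))
  age <- counts$total[counts$dimension == "age"]
  expect_equal(sum(age), 9794L)
})

test_that("count summaries respect order statistics and partitions", {
  one <- data.frame(date = as.Date("2011-01-01"), deaths_total = 5L)
  s1 <- summarize_daily_series(one)
  row <- s1$counts[s1$counts$group == "total", ]
  expect_equal(unname(unlist(row[c("mean", "min", "max")])), c(5, 5, 5))

  sim <- quick_sim(years = 2)
  s <- summarize_daily_series(sim$series)
  cc <- s$counts
  expect_true(all(cc$min <= cc$q25 & cc$q25 <= cc$median &
                    cc$median <= cc$q75 & cc$q75 <= cc$max))
  sub <- cc[cc$group != "total", ]
  expect_equal(sum(sub$total), cc$total[cc$group == "total"])
  expect_lt(abs(sum(sub$pct) - 100), 0.05)   # shares sum to 100 up to rounding
})

test_that("quartiles follow the type-7 interpolation rule", {
  # hand computation for 1..8: h = (n-1)p + 1 -> 2.75, 4.5, 6.25
  x <- 1:8
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_equal(q, c(2.75, 4.5, 6.25))
  d <- data.frame(date = seq(as.Date("2011-01-01"), by = "day", length.out = 8),
                  deaths_total = x)
  row <- summarize_daily_series(d)$counts
  expect_equal(unname(unlist(row[c("q25", "median", "q75")])),
               round(c(2.75, 4.5, 6.25)))
})

test_that("Spearman correlation is rank-based with average ranks for ties", {
  # hand-ranked oracle: x has one tie -> ranks (1, 2.5, 2.5, 4, 5, 6)
  x <- c(10, 20, 20, 30, 40, 50)
  y <- c(3, 1, 4, 9, 6, 12)
  rx <- c(1, 2.5, 2.5, 4, 5, 6)
  ry <- c(2, 1, 3, 5, 4, 6)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  sm <- spearman_matrix(data.frame(x = x, y = y), threshold = 0.6)
  expect_equal(sm$r["x", "y"], hand, tolerance = 1e-12)
  expect_true(sm$strong["x", "y"])
})

test_that("rank correlation is invariant under monotone transforms", {
  set.seed(44)
  x <- rnorm(50)
  y <- x + rnorm(50, 0, 0.5)
  r1 <- spearman_matrix(data.frame(a = x, b = y))$r["a", "b"]
  r2 <- spearman_matrix(data.frame(a = exp(x), b = y^3 + 2 * y))$r["a", "b"]
  expect_equal(r1, r2, tolerance = 1e-12)
  inc <- spearman_matrix(data.frame(a = 1:10, b = exp(1:10)))
  expect_equal(inc$r["a", "b"], 1)
})

test_that("matrix invariants hold and constants are refused", {
  sim <- quick_sim(years = 1)
  vars <- sim$series[c("temp_mean_c", "pm25", "o3_8h", "rh_pct", "bp_hpa")]
  sm <- spearman_matrix(vars)
  expect_equal(sm$r, t(sm$r))
  expect_equal(unname(diag(sm$r)), rep(1, 5))
  expect_true(all(sm$r >= -1 & sm$r <= 1))
  # the generator couples ozone positively and pressure negatively with
  # temperature, strongly enough to trip the 0.6 screen
  expect_true(sm$strong["temp_mean_c", "o3_8h"])
  expect_true(sm$strong["temp_mean_c", "bp_hpa"])
  expect_gt(sm$r["temp_mean_c", "o3_8h"], 0.6)
  expect_lt(sm$r["temp_mean_c", "bp_hpa"], -0.6)
  vars$flat <- 1
  expect_error(spearman_matrix(vars), "constant")
})
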