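test_that("knot rules place interior knots where the conventions say", {
  set.seed(3)
  v <- rnorm(500, 15, 8)

  s2 <- ns_spec(v, df = 2, knot_rule = "quantile")
  expect_length(s2$knots, 1)
  expect_equal(s2$knots, unname(quantile(v, 0.5, type = 7)))
  expect_equal(s2$boundary_knots, range(v))

  # humidity-style spline: 3 df -> knots at the 33.3rd / 66.7th percentiles
  rh <- pmin(100, pmax(10, rnorm(800, 55, 20)))
  s3 <- ns_spec(rh, df = 3, knot_rule = "quantile")
  expect_equal(s3$knots, unname(quantile(rh, c(1, 2) / 3, type = 7)))

  # lag rule: equally spaced on log(1 + lag), boundary {0, L}
  sl <- ns_spec(df = 4, knot_rule = "loglag", intercept = TRUE, max_lag = 14)
  expect_equal(sl$boundary_knots, c(0, 14))
  expect_equal(sl$knots, expm1(c(1, 2) / 3 * log1p(14)))

  # explicit knots round-trip unchanged
  se <- ns_spec(df = 3, knot_rule = "explicit", boundary_knots = c(0, 30),
                knots = c(10, 20))
  expect_equal(se$knots, c(10, 20))
  expect_equal(se$boundary_knots, c(0, 30))
})

test_that("basis dimensions always equal df and inputs are checked", {
  v <- runif(100, 0, 30)
  for (df in 1:4) {
    b <- ns_basis(ns_spec(v, df = df, knot_rule = "quantile"), v)
    expect_equal(ncol(b), df)
    expect_false(any(!is.finite(b)))
  }
  expect_error(ns_spec(c(1, 1, 1, 2), df = 3, knot_rule = "quantile"),
               "too few distinct")
  expect_error(ns_spec(df = 3, knot_rule = "explicit",
                       boundary_knots = c(0, 10), knots = c(2, 4, 6)),
               "inconsistent")
  expect_error(ns_basis(ns_spec(v, df = 2), c(1, NA, 3)), "finite")
})

test_that("natural splines reproduce linear functions exactly", {
  set.seed(4)
  x <- runif(200, -10, 35)
  y <- 2 + 3 * x
  for (df in 2:4) {
    b <- ns_basis(ns_spec(x, df = df, knot_rule = "quantile"), x)
    res <- residuals(lm(y ~ b))
    expect_lt(max(abs(res)), 1e-8)
  }
})

test_that("extrapolation beyond the boundary knots is linear", {
  x <- seq(0, 20, length.out = 80)
  spec <- ns_spec(x, df = 3, knot_rule = "quantile")
  for (grid in list(seq(21, 30, by = 0.5), seq(-12, -1, by = 0.5))) {
    b <- ns_basis(spec, grid)
    second_diff <- apply(b, 2, function(col) diff(diff(col)))
    expect_lt(max(abs(second_diff)), 1e-8)
  }
})

test_that("basis spans the truncated-power natural spline space", {
  # independent construction (truncated power basis under natural
  # constraints): with knots xi_1 < ... < xi_K (boundary included),
  # d_k(x) = [(x - xi_k)^3_+ - (x - xi_K)^3_+] / (xi_K - xi_k),
  # basis = {1, x, d_1 - d_{K-1}, ..., d_{K-2} - d_{K-1}}.
  tp_natural <- function(x, xi) {
    K <- length(xi)
    d <- function(k) (pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[k])
    cols <- lapply(seq_len(K - 2), function(k) d(k) - d(K - 1))
    cbind(1, x, do.call(cbind, cols))
  }
  xi <- c(0, 7, 13, 30)
  spec <- ns_spec(df = 3, knot_rule = "explicit",
                  boundary_knots = range(xi), knots = xi[2:3])
  pts <- c(-5, 2, 7.5, 14, 22, 29, 36)          # in-range and extrapolated
  ours <- cbind(1, ns_basis(spec, pts))
  oracle <- tp_natural(pts, xi)
  # same 4-dimensional function space: each basis explains the other exactly
  expect_lt(max(abs(residuals(lm(oracle ~ ours - 1)))), 1e-8)
  expect_lt(max(abs(residuals(lm(ours ~ oracle - 1)))), 1e-8)
})

test_that("evaluation is row-wise (permutation-equivariant)", {
  set.seed(5)
  x <- runif(60, 0, 25)
  spec <- ns_spec(x, df = 3, knot_rule = "quantile")
  perm <- sample(60)
  b <- ns_basis(spec, x)
  expect_equal(unname(b[perm, ]), unname(ns_basis(spec, x[perm])[, ]))
})

test_that("df = 1 gives a single linear column; intercept df = 1 a constant", {
  x <- seq(-5, 30, length.out = 50)
  b1 <- ns_basis(ns_spec(x, df = 1, knot_rule = "quantile"), x)
  expect_equal(ncol(b1), 1)
  expect_lt(max(abs(diff(diff(b1[, 1])))), 1e-10)   # linear everywhere
  bc <- ns_basis(ns_spec(df = 1, knot_rule = "loglag", intercept = TRUE,
                         max_lag = 0), c(0, 0, 0))
  expect_equal(unname(bc[, 1]), c(1, 1, 1))
})
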