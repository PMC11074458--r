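# Short synthetic runs and small fitted models shared across test files.

quick_sim <- function(years = 2, truth = truth_surface("null"), seed = 42, ...) {
  simulate_daily_series(sim_config(
    start_date = "2011-01-01",
    end_date = sprintf("%d-12-31", 2010 + years),
    truth = truth, random_seed = seed, ...))
}

# seasonal-ish exposure over n consecutive days
toy_exposure <- function(n, seed = 1, start = as.Date("2012-03-01")) {
  set.seed(seed)
  dates <- seq(start, by = "day", length.out = n)
  doy <- as.numeric(format(dates, "%j"))
  list(dates = dates, x = 15 - 10 * cos(2 * pi * doy / 365.25) + rnorm(n, 0, 3))
}

# small conditional Poisson fit on a toy series
toy_fit <- function(n = 400, seed = 1, L = 5, df_x = 2, df_l = 2,
                    beta_signal = 0) {
  e <- toy_exposure(n, seed)
  spec <- default_crossbasis_spec(e$x, max_lag = L, df_x = df_x, df_l = df_l)
  cb <- build_crossbasis(e$x, spec)
  strata <- assign_strata(e$dates)
  set.seed(seed + 1000)
  eta <- ifelse(is.na(cb[, 1]), 0, beta_signal * scale(e$x)[, 1])
  y <- rpois(n, exp(log(3) + eta))
  fit <- fit_conditional_poisson(cb, NULL, y, strata)
  list(fit = fit, spec = spec, cb = cb, strata = strata, y = y,
       x = e$x, dates = e$dates)
}

# independent brute-force cross-basis: explicit double loop over lags
naive_crossbasis <- function(x, spec) {
  L <- spec$max_lag
  n <- length(x)
  bl <- ns_basis(spec$lag, 0:L)
  out <- matrix(NA_real_, n, spec$exposure$df * spec$lag$df)
  for (t in seq_len(n)) {
    if (t <= L) next
    acc <- matrix(0, spec$exposure$df, spec$lag$df)
    for (l in 0:L)
      acc <- acc + outer(drop(ns_basis(spec$exposure, x[t - l])), bl[l + 1L, ])
    out[t, ] <- as.vector(t(acc))
  }
  out
}

# fabricate a minimal converged fit with chosen cross-basis coefficients
fake_fit <- function(coef_cb, spec, se = 0.1) {
  p <- length(coef_cb)
  nm <- paste0("cb", seq_len(p))
  structure(list(coef = stats::setNames(coef_cb, nm),
                 vcov = diag(se^2, p, p, names = FALSE) |>
                   `dimnames<-`(list(nm, nm)),
                 cb_cols = nm, converged = TRUE,
                 n_eff = 1000L, deviance = 0, scale = 1),
            class = "ccfit")
}
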