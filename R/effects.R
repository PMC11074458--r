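# 95% normal quantile used throughout the report tables
.z95 <- 1.959964

# contrast row over the cross-basis columns for exposure x vs ref:
# single lag l, or cumulative over 0..h
.cb_contrast <- function(spec, x, ref, lags) {
  vx <- ns_basis(spec$exposure, x) - ns_basis(spec$exposure, ref)  # 1 x df_x
  bl <- ns_basis(spec$lag, lags)                                   # h+1 x df_l
  bl_sum <- colSums(bl)
  as.vector(t(outer(drop(vx), bl_sum)))  # exposure-major (j-1)*df_l + k
}

.check_range <- function(spec, x, allow_extrapolation) {
  b <- spec$exposure$boundary_knots
  if (!allow_extrapolation && (x < b[1] || x > b[2]))
    stop("temperature ", format(x), " outside the observed range [",
         format(b[1]), ", ", format(b[2]),
         "]; set allow_extrapolation = TRUE to override", call. = FALSE)
}

.or_from_contrast <- function(fit, v_cb) {
  v <- stats::setNames(rep(0, length(fit$coef)), names(fit$coef))
  v[fit$cb_cols] <- v_cb
  logor <- sum(v * fit$coef)
  se <- sqrt(drop(v %*% fit$vcov %*% v))
  if (all(v_cb == 0)) se <- 0            # exact null contrast at the reference
  data.frame(logor = logor, se = se, or = exp(logor),
             lo = exp(logor - .z95 * se), hi = exp(logor + .z95 * se))
}

#' Single-lag odds ratio at a given temperature
#'
#' Delta-method odds ratio and 95% CI for exposure `x` versus `ref` at one
#' specific lag day: the contrast `[Bx(x) - Bx(ref)] (x) Bl(l)` applied to
#' the fitted cross-basis coefficients, with variance `v' Sigma v`.
#'
#' @param fit a [fit_conditional_poisson()] result.
#' @param spec the [crossbasis_spec()] used in the fit.
#' @param x temperature (degrees C).
#' @param ref reference temperature (degrees C), typically the MMT.
#' @param lag lag day in `0..max_lag`.
#' @param allow_extrapolation evaluate outside the observed temperature
#'   range? Default FALSE (natural-spline extrapolation is linear and easily
#'   misread).
#' @return One-row data frame: `logor`, `se`, `or`, `lo`, `hi`.
#' @export
single_lag_or <- function(fit, spec, x, ref, lag, allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "ccfit"), inherits(spec, "crossbasis_spec"))
  if (lag < 0 || lag > spec$max_lag)
    stop("lag outside 0..", spec$max_lag, call. = FALSE)
  .check_range(spec, x, allow_extrapolation)
  .or_from_contrast(fit, .cb_contrast(spec, x, ref, lag))
}

#' Cumulative odds ratio over a lag horizon
#'
#' Delta-method odds ratio and 95% CI for exposure `x` versus `ref`
#' cumulated over lags `0..horizon` (the "Lag0h" summaries): the contrast is
#' the lag-sum of the single-lag contrasts, so the cumulative log-OR equals
#' the sum of the single-lag log-ORs exactly.
#'
#' @inheritParams single_lag_or
#' @param horizon lag horizon `h` in `0..max_lag`.
#' @return One-row data frame: `logor`, `se`, `or`, `lo`, `hi`.
#' @export
cumulative_or <- function(fit, spec, x, ref, horizon, allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "ccfit"), inherits(spec, "crossbasis_spec"))
  if (horizon < 0 || horizon > spec$max_lag)
    stop("horizon outside 0..", spec$max_lag, call. = FALSE)
  .check_range(spec, x, allow_extrapolation)
  .or_from_contrast(fit, .cb_contrast(spec, x, ref, 0:horizon))
}

#' Minimum-mortality temperature
#'
#' Evaluates the overall cumulative (lag `0..max_lag`) exposure-response
#' curve on a 1,000-point equally spaced grid over the observed temperature
#' range and returns the grid temperature with the lowest cumulative risk.
#' The curve is computed against a provisional reference (the grid
#' midpoint); the minimiser does not depend on that choice. Ties are broken
#' toward the lower temperature.
#'
#' @param fit a [fit_conditional_poisson()] result (must have converged).
#' @param spec the [crossbasis_spec()] used in the fit.
#' @param grid_size number of grid points (default 1000).
#' @return The MMT in degrees C, with the evaluation grid and curve attached
#'   as attributes `"grid"` and `"curve"` (cumulative log-OR vs the
#'   provisional reference).
#' @export
find_mmt <- function(fit, spec, grid_size = 1000L) {
  stopifnot(inherits(fit, "ccfit"), inherits(spec, "crossbasis_spec"))
  if (!fit$converged) stop("fit did not converge; MMT undefined", call. = FALSE)
  b <- spec$exposure$boundary_knots
  grid <- seq(b[1], b[2], length.out = grid_size)
  ref0 <- grid[ceiling(grid_size / 2)]
  curve <- vapply(grid, function(x)
    sum(.cb_contrast(spec, x, ref0, 0:spec$max_lag) * fit$coef[fit$cb_cols]),
    numeric(1))
  if (any(!is.finite(curve))) stop("non-finite exposure-response curve", call. = FALSE)
  mmt <- grid[which.min(curve)]          # which.min -> first = lowest temperature
  structure(mmt, grid = grid, curve = curve)
}

#' Extreme temperature thresholds
#'
#' Type-7 (linear-interpolation) percentiles of the observed daily mean
#' temperatures, defining the extreme-low and extreme-high thresholds (main
#' analysis: 1st and 99th percentiles).
#'
#' @param temperatures observed daily mean temperatures.
#' @param p_low,p_high percentiles in (0, 100) with `p_low < p_high`.
#' @return Named numeric vector `c(low = ..., high = ...)`.
#' @export
extreme_thresholds <- function(temperatures, p_low = 1, p_high = 99) {
  if (length(temperatures) == 0) stop("empty temperature series", call. = FALSE)
  if (!(p_low > 0 && p_low < p_high && p_high < 100))
    stop("need 0 < p_low < p_high < 100", call. = FALSE)
  q <- stats::quantile(temperatures, c(p_low, p_high) / 100, type = 7,
                       names = FALSE, na.rm = TRUE)
  c(low = q[1], high = q[2])
}

#' Single-lag and cumulative effect table
#'
#' Tabulates, for each requested temperature, the single-lag odds ratio at
#' every lag `0..max_lag` and the cumulative odds ratio at every horizon,
#' all referenced to `ref` (typically the fitted MMT). This is the payload
#' behind "Lag0h" report tables and lag-response curves.
#'
#' @inheritParams single_lag_or
#' @param temperatures temperatures (degrees C) to tabulate.
#' @return A data frame of class `"effect_table"` with columns `type`
#'   (`"single"`/`"cumulative"`), `temp`, `lag` (lag day or horizon),
#'   `logor`, `se`, `or`, `lo`, `hi`, and attributes `"ref"`.
#' @export
effect_table <- function(fit, spec, temperatures, ref, allow_extrapolation = FALSE) {
  rows <- list()
  for (x in temperatures) {
    for (l in 0:spec$max_lag) {
      rows[[length(rows) + 1L]] <- cbind(
        type = "single", temp = x, lag = l,
        single_lag_or(fit, spec, x, ref, l, allow_extrapolation))
      rows[[length(rows) + 1L]] <- cbind(
        type = "cumulative", temp = x, lag = l,
        cumulative_or(fit, spec, x, ref, l, allow_extrapolation))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ref") <- ref
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Overall cumulative exposure-response curve
#'
#' The cumulative (lag `0..max_lag`) odds ratio with 95% CI on an equally
#' spaced temperature grid over the observed range, referenced to `ref`.
#'
#' @inheritParams single_lag_or
#' @param grid_size number of grid points (default 200).
#' @return Data frame with `temp`, `logor`, `se`, `or`, `lo`, `hi`.
#' @export
overall_curve <- function(fit, spec, ref, grid_size = 200L) {
  b <- spec$exposure$boundary_knots
  grid <- seq(b[1], b[2], length.out = grid_size)
  out <- do.call(rbind, lapply(grid, function(x)
    cumulative_or(fit, spec, x, ref, spec$max_lag)))
  cbind(temp = grid, out)
}
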