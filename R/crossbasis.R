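#' Specify an exposure-lag cross-basis
#'
#' Combines an exposure spline spec and a lag spline spec into the
#' description of a bivariate cross-basis over exposure value and lag,
#' the design at the heart of a distributed lag nonlinear model. The lag
#' basis must have boundary knots exactly at 0 and `max_lag`.
#'
#' @param exposure_spec a [ns_spec()] for the exposure dimension
#'   (conventionally without intercept: the constant is absorbed by the
#'   case-crossover stratum effects).
#' @param lag_spec a [ns_spec()] for the lag dimension (conventionally with
#'   intercept so unlagged effects are representable).
#' @param max_lag maximum lag in days (L >= 0).
#' @return An object of class `"crossbasis_spec"`.
#' @export
crossbasis_spec <- function(exposure_spec, lag_spec, max_lag) {
  stopifnot(inherits(exposure_spec, "spline_spec"), inherits(lag_spec, "spline_spec"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("`max_lag` must be >= 0", call. = FALSE)
  if (!(max_lag == 0L && lag_spec$df == 1L) &&
      !isTRUE(all.equal(lag_spec$boundary_knots, c(0, max_lag))))
    stop("lag spec boundary knots must be exactly {0, max_lag}", call. = FALSE)
  structure(list(exposure = exposure_spec, lag = lag_spec, max_lag = max_lag),
            class = "crossbasis_spec")
}

#' Default cross-basis specification for a temperature series
#'
#' Convenience constructor using the conventional defaults: natural cubic
#' splines with `df_x` columns in exposure (quantile knots, boundary at the
#' observed range) and `df_l` columns in lag (intercept included, knots
#' equally spaced on the log(1 + lag) scale, boundary at 0 and `max_lag`).
#'
#' @param exposure observed exposure series (degrees C).
#' @param max_lag maximum lag in days (default 14).
#' @param df_x,df_l basis dimensions for exposure and lag (default 2 each).
#' @return A `"crossbasis_spec"`.
#' @export
default_crossbasis_spec <- function(exposure, max_lag = 14L, df_x = 2L, df_l = 2L) {
  crossbasis_spec(
    exposure_spec = ns_spec(exposure, df = df_x, knot_rule = "quantile"),
    lag_spec = ns_spec(df = df_l, knot_rule = "loglag", intercept = TRUE,
                       max_lag = max_lag),
    max_lag = max_lag)
}

#' Build cross-basis design columns from a daily exposure series
#'
#' Row `t`, column `(j, k)` of the result is the lag-summed tensor product
#' `sum_{l = 0..L} Bx_j(x[t - l]) * Bl_k(l)`: the contribution of the
#' exposure history of day `t` to the distributed-lag design. Columns are
#' ordered exposure-major (`(j - 1) * df_l + k`). The first `L` days lack a
#' full history; their rows are `NA` and flagged invalid (dropped at fit
#' time), never silently zeroed.
#'
#' @param exposure numeric vector, one exposure value per consecutive day.
#' @param spec a [crossbasis_spec()].
#' @return A numeric matrix of class `"crossbasis"` with
#'   `df_x * df_l` columns and attributes `"spec"` and `"valid"` (logical
#'   mask of rows with complete history).
#' @export
build_crossbasis <- function(exposure, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  if (!is.numeric(exposure) || anyNA(exposure) || any(!is.finite(exposure)))
    stop("exposure series must be finite, with no missing days", call. = FALSE)
  n <- length(exposure)
  L <- spec$max_lag
  if (n < L + 1L)
    stop("exposure series must have at least max_lag + 1 = ", L + 1L, " days",
         call. = FALSE)
  bx <- ns_basis(spec$exposure, exposure)          # n x df_x
  bl <- ns_basis(spec$lag, 0:L)                    # (L+1) x df_l
  df_x <- spec$exposure$df
  df_l <- spec$lag$df
  cb <- matrix(0, nrow = n, ncol = df_x * df_l)
  jx <- rep(seq_len(df_x), each = df_l)            # exposure-major ordering
  kx <- rep(seq_len(df_l), times = df_x)
  for (l in 0:L) {
    rows <- (L + 1L):n                             # rows with full history
    cb[rows, ] <- cb[rows, , drop = FALSE] +
      bx[rows - l, jx, drop = FALSE] *
      matrix(bl[l + 1L, kx], nrow = length(rows), ncol = df_x * df_l, byrow = TRUE)
  }
  valid <- rep(TRUE, n)
  if (L > 0L) {
    valid[seq_len(L)] <- FALSE
    cb[seq_len(L), ] <- NA_real_
  }
  colnames(cb) <- paste0("cb.x", jx, ".l", kx)
  structure(cb, spec = spec, valid = valid, class = c("crossbasis", "matrix", "array"))
}

#' @export
print.crossbasis <- function(x, ...) {
  sp <- attr(x, "spec")
  cat("Cross-basis matrix:", nrow(x), "days x", ncol(x), "columns",
      sprintf("(df_x = %d, df_l = %d, max lag = %d)\n",
              sp$exposure$df, sp$lag$df, sp$max_lag))
  cat(" ", sum(!attr(x, "valid")), "leading days without full exposure history\n")
  invisible(x)
}
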