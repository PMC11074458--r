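#' Specify a natural cubic spline basis
#'
#' Builds the description of a natural cubic spline basis (knot locations,
#' boundary knots, intercept handling) from which design columns can later be
#' evaluated with [ns_basis()]. Three knot rules are supported:
#'
#' * `"quantile"` — interior knots at equally spaced sample quantiles of
#'   `values` (type-7 interpolation), boundary knots at the observed range.
#'   This is the conventional rule for exposure and confounder splines.
#' * `"loglag"` — interior knots equally spaced on the `log(1 + lag)` scale
#'   with boundary knots at 0 and `max_lag`; the conventional rule for the
#'   lag dimension of a distributed-lag basis.
#' * `"explicit"` — knots supplied directly via `knots` / `boundary_knots`.
#'
#' The number of basis columns always equals `df`. Without an intercept a
#' natural spline with `k` interior knots has `k + 1` columns, so the quantile
#' and loglag rules place `df - 1` (or `df - 2` with `intercept = TRUE`)
#' interior knots. `df = 1` without intercept yields the single linear natural
#' spline column; `df = 1` with intercept yields a constant column (useful for
#' a degenerate lag basis).
#'
#' @param values numeric vector the basis is intended for; required by the
#'   quantile rule, ignored by the others.
#' @param df integer, number of basis columns (>= 1).
#' @param knot_rule one of `"quantile"`, `"loglag"`, `"explicit"`.
#' @param boundary_knots length-2 numeric, required for `"explicit"`.
#' @param knots interior knots for `"explicit"`.
#' @param intercept logical; should the basis span the constant function?
#' @param max_lag maximum lag in days, required for `"loglag"`.
#' @return An object of class `"spline_spec"`.
#' @seealso [ns_basis()], [crossbasis_spec()]
#' @export
ns_spec <- function(values = NULL, df, knot_rule = c("quantile", "loglag", "explicit"),
                    boundary_knots = NULL, knots = NULL, intercept = FALSE,
                    max_lag = NULL) {
  knot_rule <- match.arg(knot_rule)
  df <- as.integer(df)
  if (df < 1L) stop("`df` must be a positive integer", call. = FALSE)
  n_interior <- df - 1L - as.integer(intercept)
  if (n_interior < -1L || (n_interior == -1L && !intercept))
    stop("`df` too small for the requested basis", call. = FALSE)

  if (knot_rule == "quantile") {
    if (is.null(values) || !is.numeric(values))
      stop("the quantile rule needs the sample `values`", call. = FALSE)
    values <- values[is.finite(values)]
    if (length(unique(values)) < df + 1L)
      stop("too few distinct values for df = ", df, call. = FALSE)
    boundary_knots <- range(values)
    knots <- if (n_interior > 0L)
      unname(stats::quantile(values, probs = seq_len(n_interior) / (n_interior + 1L),
                             type = 7, names = FALSE))
    else numeric(0)
  } else if (knot_rule == "loglag") {
    if (is.null(max_lag) || max_lag < 0)
      stop("the loglag rule needs a non-negative `max_lag`", call. = FALSE)
    boundary_knots <- c(0, max_lag)
    knots <- if (n_interior > 0L)
      expm1(seq_len(n_interior) / (n_interior + 1L) * log1p(max_lag))
    else numeric(0)
    if (max_lag == 0 && df > 1L)
      stop("max_lag = 0 admits only a single-column lag basis", call. = FALSE)
  } else {
    if (is.null(boundary_knots) || length(boundary_knots) != 2L)
      stop("explicit rule needs length-2 `boundary_knots`", call. = FALSE)
    if (is.null(knots)) knots <- numeric(0)
    if (length(knots) != max(n_interior, 0L))
      stop("df = ", df, " is inconsistent with ", length(knots),
           " explicit interior knots", call. = FALSE)
  }

  if (boundary_knots[1] >= boundary_knots[2] && !(df == 1L && intercept))
    stop("boundary knots must be strictly increasing", call. = FALSE)
  if (length(knots) > 0) {
    if (any(diff(knots) <= 0)) stop("interior knots must be strictly increasing", call. = FALSE)
    if (any(knots <= boundary_knots[1] | knots >= boundary_knots[2]))
      stop("interior knots must lie strictly inside the boundary knots", call. = FALSE)
  }

  structure(
    list(df = df, knots = as.numeric(knots),
         boundary_knots = as.numeric(boundary_knots),
         intercept = isTRUE(intercept), knot_rule = knot_rule),
    class = "spline_spec")
}

#' Evaluate a natural cubic spline basis
#'
#' Returns the design columns of the natural cubic spline described by a
#' [ns_spec()] at the requested points: piecewise cubic, twice continuously
#' differentiable, and linear beyond the boundary knots (points outside the
#' boundary are linearly extrapolated). Row `i` depends only on `points[i]`.
#'
#' @param spec a `"spline_spec"`.
#' @param points numeric vector of evaluation points; must be finite.
#' @return A numeric matrix with `length(points)` rows and `spec$df` columns,
#'   carrying the producing spec in attribute `"spec"`.
#' @export
ns_basis <- function(spec, points) {
  stopifnot(inherits(spec, "spline_spec"))
  if (!is.numeric(points) || anyNA(points) || any(!is.finite(points)))
    stop("evaluation points must be finite numbers", call. = FALSE)
  if (spec$df == 1L && spec$intercept) {
    m <- matrix(1, nrow = length(points), ncol = 1L)
  } else {
    m <- splines::ns(points, knots = spec$knots,
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
    m <- matrix(as.numeric(m), nrow = length(points), ncol = spec$df)
  }
  colnames(m) <- paste0("ns", seq_len(spec$df))
  attr(m, "spec") <- spec
  attr(m, "points") <- as.numeric(points)
  m
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Natural cubic spline spec: df =", x$df,
      if (x$intercept) "(with intercept)" else "", "\n")
  cat("  rule:", x$knot_rule,
      " boundary: [", format(x$boundary_knots[1]), ",",
      format(x$boundary_knots[2]), "]\n")
  if (length(x$knots))
    cat("  interior knots:", paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Generalized cross-validation score of a fitted model
#'
#' Computes the GLM form of the generalized cross-validation score,
#' `GCV = n * D / (n - p)^2`, where `D` is the model deviance, `n` the
#' effective number of observations, and `p` the number of estimated
#' non-stratum parameters. Smaller is better; the score can be used to
#' compare cross-basis or confounder `df` choices on the same data.
#'
#' @param fit a `"ccfit"` object from [fit_conditional_poisson()].
#' @return A single numeric GCV score.
#' @export
gcv_score <- function(fit) {
  stopifnot(inherits(fit, "ccfit"))
  n <- fit$n_eff
  p <- length(fit$coef)
  n * fit$deviance / (n - p)^2
}
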