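#' Assign time-stratified case-crossover strata
#'
#' Labels every day by its (calendar year, calendar month, ISO weekday)
#' triple. Within a stratum every day shares the year, month and day of the
#' week, so each case day has the 3 or 4 other same-weekday days of its
#' month as self-matched referents ("up to 4 control days per case").
#' Assignment is deterministic and independent of input order.
#'
#' @param dates a `Date` vector (or anything `as.Date()` accepts); need not
#'   be contiguous or sorted.
#' @return An object of class `"stratum_index"`: a list with `dates`,
#'   `label` (factor, one level per stratum, aligned with `dates`) and
#'   `sizes` (named integer vector of stratum sizes).
#' @export
assign_strata <- function(dates) {
  d <- as.Date(dates)
  if (anyNA(d)) stop("invalid dates in stratum assignment", call. = FALSE)
  lt <- as.POSIXlt(d)
  iso_wd <- ((lt$wday + 6L) %% 7L) + 1L  # ISO: Monday = 1 ... Sunday = 7
  lab <- sprintf("%04d-%02d-wd%d", lt$year + 1900L, lt$mon + 1L, iso_wd)
  label <- factor(lab, levels = sort(unique(lab)))
  structure(list(dates = d, label = label,
                 sizes = c(table(label))),
            class = "stratum_index")
}

#' @export
print.stratum_index <- function(x, ...) {
  cat("Time-stratified case-crossover index:", length(x$dates), "days in",
      nlevels(x$label), "year x month x weekday strata\n")
  cat("  stratum sizes:", paste(names(table(x$sizes)), "days x",
                                table(x$sizes), collapse = "; "), "\n")
  invisible(x)
}

#' Screen pollutants against temperature collinearity
#'
#' Returns the pollutant columns whose absolute Spearman correlation with
#' daily mean temperature is below `threshold`. Pollutants at or above the
#' threshold are considered strongly temperature-correlated and excluded
#' from the default adjustment set to avoid collinearity with the exposure
#' cross-basis.
#'
#' @param series a daily series (see [simulate_daily_series()] for the
#'   column layout).
#' @param pollutants candidate column names.
#' @param threshold absolute Spearman correlation cutoff (default 0.6).
#' @return Character vector of retained pollutant names.
#' @export
select_pollutants <- function(series,
                              pollutants = c("pm25", "pm10", "so2", "no2", "co", "o3_8h"),
                              threshold = 0.6) {
  pollutants <- intersect(pollutants, names(series))
  keep <- vapply(pollutants, function(p) {
    r <- stats::cor(series$temp_mean_c, series[[p]], method = "spearman",
                    use = "complete.obs")
    abs(r) < threshold
  }, logical(1))
  pollutants[keep]
}

#' Build the confounder design matrix
#'
#' Concatenates natural cubic spline expansions (quantile knots, no
#' intercept) of relative humidity and each selected pollutant. Defaults
#' follow the usual adjustment choices for temperature-health models:
#' humidity at 3 df and each pollutant at 2 df. Other continuous covariates
#' (e.g. barometric pressure, wind speed) can be added through `extra`,
#' expanded at `pollutant_df`.
#'
#' @param series a daily series data frame.
#' @param pollutants pollutant column names to adjust for; `"auto"` applies
#'   [select_pollutants()].
#' @param humidity_df spline df for relative humidity (default 3).
#' @param pollutant_df spline df for each pollutant (default 2).
#' @param include_humidity adjust for `rh_pct`? (default TRUE)
#' @param extra further covariate column names expanded at `pollutant_df`.
#' @return A numeric matrix of class `"confounder_design"` whose column
#'   names trace each column to its source variable (`"<var>.ns<k>"`).
#' @export
build_confounder_design <- function(series, pollutants = "auto",
                                    humidity_df = 3L, pollutant_df = 2L,
                                    include_humidity = TRUE,
                                    extra = character()) {
  if (identical(pollutants, "auto")) pollutants <- select_pollutants(series)
  vars <- c(if (include_humidity) "rh_pct", pollutants, extra)
  dfs <- c(if (include_humidity) humidity_df,
           rep(pollutant_df, length(pollutants) + length(extra)))
  missing_vars <- setdiff(vars, names(series))
  if (length(missing_vars))
    stop("unknown confounder column(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  if (length(vars) == 0L) {
    m <- matrix(numeric(0), nrow = nrow(series), ncol = 0L)
    return(structure(m, class = c("confounder_design", "matrix", "array")))
  }
  blocks <- mapply(function(v, k) {
    x <- series[[v]]
    if (anyNA(x) || any(!is.finite(x)))
      stop("confounder `", v, "` has missing or non-finite values", call. = FALSE)
    if (length(unique(x)) < k + 1L)
      stop("confounder `", v, "` is (nearly) constant; spline undefined", call. = FALSE)
    b <- ns_basis(ns_spec(x, df = k, knot_rule = "quantile"), x)
    colnames(b) <- paste0(v, ".ns", seq_len(k))
    b
  }, vars, dfs, SIMPLIFY = FALSE)
  m <- do.call(cbind, blocks)
  structure(m, variables = vars, class = c("confounder_design", "matrix", "array"))
}
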