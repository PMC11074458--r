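#' Published registry subgroup totals
#'
#' The published 2011-2020 Jinan road-traffic-fatality totals by sex, age
#' group and transport mode (deaths over the whole decade). These are the
#' printed summary counts only — the underlying daily series is not public —
#' and are used for descriptive arithmetic (group sums and percentage
#' shares) and as calibration anchors for the synthetic generator.
#'
#' @return Data frame with columns `dimension`, `group`, `total`.
#' @export
jinan_published_counts <- function() {
  data.frame(
    dimension = c("sex", "sex",
                  "age", "age", "age",
                  "transport", "transport", "transport", "transport", "transport"),
    group = c("male", "female",
              "0-34", "35-64", "65+",
              "walking", "bicycle", "motorcycle", "motorvehicle", "other"),
    total = c(7151L, 2643L,
              1810L, 5613L, 2371L,
              4495L, 1474L, 1654L, 1591L, 580L))
}

#' Percentage shares within a partition
#'
#' @param totals integer group totals forming a partition.
#' @param digits decimals to round to (default 2; trailing zeros drop when
#'   printed, matching conventional table formatting).
#' @return Numeric shares in percent, summing to 100 up to rounding.
#' @export
percent_share <- function(totals, digits = 2) {
  round(100 * totals / sum(totals), digits)
}

#' Descriptive summary of a daily series
#'
#' Per-subgroup daily-count summaries (mean, min, quartiles, max, all
#' rounded to integers as in conventional mortality tables), decade totals
#' and percentage shares of the grand total, plus continuous summaries
#' (unrounded) for the meteorological and pollutant columns.
#'
#' @param series a `daily_series` data frame.
#' @return A list of class `"series_summary"` with data frames `counts` and
#'   `exposures`.
#' @export
summarize_daily_series <- function(series) {
  validate_daily_series(series, required = c("date", "deaths_total"))
  count_cols <- grep("^deaths_", names(series), value = TRUE)
  qrow <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(mean = mean(x), min = min(x), q25 = q[1], median = q[2], q75 = q[3],
      max = max(x))
  }
  counts <- do.call(rbind, lapply(count_cols, function(col) {
    x <- series[[col]]
    if (length(x) == 0) stop("empty group: ", col, call. = FALSE)
    data.frame(group = sub("^deaths_", "", col),
               t(round(qrow(x))), total = sum(x))
  }))
  grand <- counts$total[counts$group == "total"]
  counts$pct <- if (length(grand) == 1 && grand > 0)
    round(100 * counts$total / grand, 2) else NA_real_
  expo_cols <- intersect(c("temp_mean_c", "rh_pct", "bp_hpa", "ws_ms",
                           "pm25", "pm10", "no2", "co", "so2", "o3_8h"),
                         names(series))
  exposures <- do.call(rbind, lapply(expo_cols, function(col)
    data.frame(variable = col, t(qrow(series[[col]])))))
  structure(list(counts = counts, exposures = exposures),
            class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat("Daily death counts by subgroup:\n")
  print(x$counts, row.names = FALSE, digits = 4)
  cat("\nDaily exposures and confounders:\n")
  print(x$exposures, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Spearman correlation matrix with strong-correlation flags
#'
#' Rank-based correlation (average ranks for ties) between the supplied
#' daily variables, with a logical flag matrix marking pairs whose absolute
#' correlation meets the strong-correlation threshold (default 0.6), the
#' screen used to drop temperature-collinear pollutants from the adjustment
#' set.
#'
#' @param variables data frame of named daily series (numeric columns).
#' @param threshold absolute correlation defining "strong" (default 0.6).
#' @return A list of class `"spearman_matrix"` with `r` (correlations,
#'   rounded to 3 decimals in the print method, stored in full precision)
#'   and `strong` (logical, diagonal `NA`).
#' @export
spearman_matrix <- function(variables, threshold = 0.6) {
  variables <- as.data.frame(variables)
  num <- vapply(variables, is.numeric, logical(1))
  variables <- variables[num]
  if (nrow(variables) < 3) stop("need at least 3 complete days", call. = FALSE)
  const <- vapply(variables, function(x) stats::sd(x, na.rm = TRUE) == 0, logical(1))
  if (any(const))
    stop("constant variable(s): ", paste(names(variables)[const], collapse = ", "),
         "; rank correlation undefined", call. = FALSE)
  r <- stats::cor(variables, method = "spearman", use = "pairwise.complete.obs")
  strong <- abs(r) >= threshold
  diag(strong) <- NA
  structure(list(r = r, strong = strong, threshold = threshold),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("Spearman correlations (|r| >=", x$threshold, "flagged strong):\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Write descriptive report tables
#'
#' Emits the subgroup-count summary, exposure summary and Spearman matrix as
#' tab-separated text files.
#'
#' @param series a `daily_series`.
#' @param out_dir output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_descriptive_tables <- function(series, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- summarize_daily_series(series)
  vars <- series[intersect(c("temp_mean_c", "pm25", "pm10", "no2", "so2", "co",
                             "o3_8h", "rh_pct", "bp_hpa", "ws_ms"), names(series))]
  sm <- spearman_matrix(vars)
  p1 <- file.path(out_dir, "summary_counts.tsv")
  p2 <- file.path(out_dir, "summary_exposures.tsv")
  p3 <- file.path(out_dir, "spearman_matrix.tsv")
  utils::write.table(s$counts, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s$exposures, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(sm$r, 3), p3, sep = "\t", quote = FALSE)
  invisible(c(p1, p2, p3))
}
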