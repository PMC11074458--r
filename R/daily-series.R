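#' @keywords internal
daily_series_columns <- function() {
  c("date", "deaths_total", "deaths_walking", "deaths_bicycle",
    "deaths_motorcycle", "deaths_motorvehicle", "deaths_other",
    "temp_mean_c", "rh_pct", "bp_hpa", "ws_ms",
    "pm25", "pm10", "so2", "no2", "co", "o3_8h")
}

#' Validate a daily series table
#'
#' Checks the fixed column schema (ISO dates, death counts per transport
#' mode, daily mean temperature, relative humidity, barometric pressure,
#' wind speed and six pollutants), count non-negativity, and that rows are
#' one-per-day. Missing required columns are reported by name.
#'
#' @param series a data frame.
#' @param required columns that must be present (default: the full schema).
#' @return The series, invisibly, with class `daily_series` attached.
#' @export
validate_daily_series <- function(series, required = daily_series_columns()) {
  missing_cols <- setdiff(required, names(series))
  if (length(missing_cols))
    stop("daily series is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- as.Date(series$date)
  if (anyNA(d)) stop("unparseable dates in `date` column", call. = FALSE)
  if (anyDuplicated(d)) stop("duplicate dates in daily series", call. = FALSE)
  counts <- series[grep("^deaths_", names(series))]
  if (any(vapply(counts, function(x) any(x < 0, na.rm = TRUE), logical(1))))
    stop("negative death counts", call. = FALSE)
  if (!inherits(series, "daily_series"))
    class(series) <- c("daily_series", class(series))
  invisible(series)
}

#' Write a daily series (and optional truth sidecar) to delimited text
#'
#' The series is written as tab-separated text with ISO-8601 dates and
#' missing values as empty fields. When a truth surface is supplied a
#' sidecar JSON file `<path>.truth.json` records its form, parameters and
#' the generating seed, so every simulated number is regenerable.
#'
#' @param x a `daily_series` data frame or a `sim_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(x, path) {
  truth <- NULL; seed <- NULL
  if (inherits(x, "sim_result")) {
    truth <- x$truth; seed <- x$config$random_seed; x <- x$series
  }
  out <- x
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (!is.null(truth)) {
    side <- list(form = truth$form, max_lag = truth$max_lag, ref = truth$ref,
                 params = truth$params, slope = truth$slope,
                 random_seed = seed)
    jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                         paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a daily series from delimited text
#'
#' @param path path to a file written in the layout of
#'   [write_daily_series()] (tab- or comma-separated is auto-detected).
#' @param drop_incomplete drop rows with missing exposure/confounders and
#'   report how many were dropped (default TRUE).
#' @return A validated `daily_series` data frame.
#' @export
read_daily_series <- function(path, drop_incomplete = TRUE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  series <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, na.strings = c("", "NA"))
  series <- validate_daily_series(series)
  series$date <- as.Date(series$date)
  if (drop_incomplete) {
    num <- setdiff(daily_series_columns(), "date")
    ok <- stats::complete.cases(series[num])
    if (any(!ok)) {
      message(sum(!ok), " row(s) with missing values dropped")
      series <- series[ok, , drop = FALSE]
    }
  }
  series
}
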