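#' Analysis configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults are the main
#' model: lag window 0-14 days, natural cubic splines with 2 df in both the
#' exposure and lag dimensions, humidity at 3 df, each retained pollutant at
#' 2 df (pollutants screened by |Spearman r| < 0.6 against temperature),
#' extremes at the 1st/99th percentiles, and per-transport-mode subgroup
#' models sharing the same design. The sensitivity grid crosses lag windows
#' {7, 14, 21} x humidity df {2, 3, 4} x percentile pairs
#' {(1,99), (2.5,97.5), (10,90)}.
#'
#' @param max_lag lag window L in days (default 14).
#' @param exposure_df,lag_df cross-basis dimensions (default 2 and 2).
#' @param humidity_df,pollutant_df confounder spline df (defaults 3 and 2).
#' @param pollutants `"auto"` (screen with [select_pollutants()]) or an
#'   explicit character vector.
#' @param p_low,p_high extreme-temperature percentiles (defaults 1 and 99).
#' @param subgroups outcome columns to model; the residual "other" category
#'   is summarised but never modelled.
#' @param sensitivity_lags,sensitivity_dfs,sensitivity_percentiles the
#'   sensitivity grid axes.
#' @param sensitivity_subgroups subgroups run through the sensitivity grid
#'   (default `"total"`).
#' @param seed integer seed recorded in the provenance block.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(max_lag = 14L, exposure_df = 2L, lag_df = 2L,
                            humidity_df = 3L, pollutant_df = 2L,
                            pollutants = "auto", p_low = 1, p_high = 99,
                            subgroups = c("total", "walking", "bicycle",
                                          "motorcycle", "motorvehicle"),
                            sensitivity_lags = c(7L, 14L, 21L),
                            sensitivity_dfs = c(2L, 3L, 4L),
                            sensitivity_percentiles = list(c(1, 99), c(2.5, 97.5),
                                                           c(10, 90)),
                            sensitivity_subgroups = "total",
                            seed = 1L) {
  if (max_lag < 0L) stop("`max_lag` must be >= 0", call. = FALSE)
  if (any(c(exposure_df, lag_df, humidity_df, pollutant_df) < 1L))
    stop("all spline df must be >= 1", call. = FALSE)
  if (!(p_low > 0 && p_low < p_high && p_high < 100))
    stop("need 0 < p_low < p_high < 100", call. = FALSE)
  structure(as.list(environment()), class = "analysis_config")
}

# stable provenance fingerprint of a configuration
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

# fit one subgroup and derive its reportables; errors become a logged record
.fit_subgroup <- function(series, subgroup, config) {
  counts <- series[[paste0("deaths_", sub("^total$", "total", subgroup))]]
  spec <- default_crossbasis_spec(series$temp_mean_c, max_lag = config$max_lag,
                                  df_x = config$exposure_df, df_l = config$lag_df)
  cb <- build_crossbasis(series$temp_mean_c, spec)
  conf <- build_confounder_design(series, pollutants = config$pollutants,
                                  humidity_df = config$humidity_df,
                                  pollutant_df = config$pollutant_df)
  strata <- assign_strata(series$date)
  fit <- fit_conditional_poisson(cb, conf, counts, strata)
  thr <- extreme_thresholds(series$temp_mean_c, config$p_low, config$p_high)
  mmt <- find_mmt(fit, spec)
  # two-pass reference handling: all tables re-centred on the fitted MMT
  eff <- effect_table(fit, spec, temperatures = unname(thr), ref = as.numeric(mmt))
  curve <- overall_curve(fit, spec, ref = as.numeric(mmt))
  list(subgroup = subgroup, fit = fit, spec = spec,
       thresholds = thr, mmt = as.numeric(mmt),
       effects = eff, curve = curve, error = NULL)
}

#' Run the full case-crossover distributed-lag analysis
#'
#' For each configured subgroup: assigns year-month-weekday strata, builds
#' the temperature cross-basis and confounder design, fits the conditional
#' Poisson model, locates the minimum-mortality temperature, and tabulates
#' single-lag and cumulative odds ratios at the extreme-temperature
#' thresholds (horizons `Lag0 0..L`) plus the overall cumulative
#' exposure-response curve. Descriptive tables are always produced. A
#' subgroup whose fit fails is recorded with its error message; the run
#' continues.
#'
#' @param series a `daily_series` data frame or a path to one on disk.
#' @param config an [analysis_config()].
#' @param out_dir if non-NULL, write report tables and a run manifest here.
#' @return A list of class `"run_report"`: `descriptives`, `spearman`,
#'   `thresholds`, per-subgroup results in `models`, and `provenance`.
#' @export
run_analysis <- function(series, config = analysis_config(), out_dir = NULL) {
  if (is.character(series)) series <- read_daily_series(series)
  series <- validate_daily_series(series)
  series <- series[order(as.Date(series$date)), , drop = FALSE]
  if (identical(config$pollutants, "auto"))
    config$pollutants <- select_pollutants(series)

  descr <- summarize_daily_series(series)
  sm <- spearman_matrix(series[intersect(
    c("temp_mean_c", "pm25", "pm10", "no2", "so2", "co", "o3_8h",
      "rh_pct", "bp_hpa", "ws_ms"), names(series))])
  models <- lapply(config$subgroups, function(g)
    tryCatch(.fit_subgroup(series, g, config),
             error = function(e) list(subgroup = g, error = conditionMessage(e))))
  names(models) <- config$subgroups

  report <- structure(
    list(descriptives = descr, spearman = sm,
         thresholds = extreme_thresholds(series$temp_mean_c, config$p_low,
                                         config$p_high),
         models = models,
         provenance = list(config = unclass(config),
                           config_hash = .config_hash(config),
                           seed = config$seed,
                           package_version = as.character(
                             utils::packageVersion("templag")),
                           n_days = nrow(series))),
    class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, series, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Case-crossover DLNM run over", x$provenance$n_days, "days\n")
  cat("  extreme thresholds:", format(x$thresholds["low"], digits = 3), "/",
      format(x$thresholds["high"], digits = 3), "degrees C\n")
  for (m in x$models) {
    if (!is.null(m$error)) {
      cat("  ", m$subgroup, ": FAILED -", m$error, "\n")
    } else {
      top <- m$effects[m$effects$type == "cumulative" &
                         m$effects$lag == m$spec$max_lag, ]
      cat(sprintf("  %-13s MMT %6.1f C; cumulative OR(lag 0-%d) low %.3f, high %.3f\n",
                  m$subgroup, m$mmt, m$spec$max_lag, top$or[1], top$or[2]))
    }
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits per-subgroup effect tables and curves, descriptive tables, and a
#' JSON manifest with the provenance block (config, hash, seed, version),
#' all as delimited/structured text. Report tables round odds ratios to 3
#' decimals.
#'
#' @param report a `"run_report"`.
#' @param series the analysed `daily_series` (for the descriptive tables).
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, series, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_descriptive_tables(series, out_dir)
  for (m in report$models) {
    if (!is.null(m$error)) next
    eff <- m$effects
    eff[c("or", "lo", "hi")] <- lapply(eff[c("or", "lo", "hi")], round, 3)
    utils::write.table(eff, file.path(out_dir, paste0("effects_", m$subgroup, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(m$curve, file.path(out_dir, paste0("curve_", m$subgroup, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  failures <- Filter(function(m) !is.null(m$error), report$models)
  manifest <- c(report$provenance,
                list(thresholds = as.list(report$thresholds),
                     mmt = lapply(Filter(function(m) is.null(m$error),
                                         report$models), `[[`, "mmt"),
                     failures = lapply(failures, `[[`, "error")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}

#' Run the sensitivity grid
#'
#' Re-runs the analysis over the full grid of lag windows, humidity
#' (meteorological-confounder) df and extreme-percentile pairs — 3 x 3 x 3 =
#' 27 cells per subgroup by default — and assembles a comparison table of
#' cumulative odds ratios at the cell's extreme thresholds over its full lag
#' window. The cell matching the main configuration reproduces the main
#' run's estimates exactly.
#'
#' @inheritParams run_analysis
#' @return A list of class `"sensitivity_report"`: `grid` (the comparison
#'   data frame with one row per cell x subgroup x extreme) and `provenance`.
#' @export
run_sensitivity <- function(series, config = analysis_config(), out_dir = NULL) {
  if (is.character(series)) series <- read_daily_series(series)
  series <- validate_daily_series(series)
  if (identical(config$pollutants, "auto"))
    config$pollutants <- select_pollutants(series)
  cells <- expand.grid(max_lag = config$sensitivity_lags,
                       humidity_df = config$sensitivity_dfs,
                       pct = seq_along(config$sensitivity_percentiles))
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$max_lag <- cells$max_lag[i]
    cfg$humidity_df <- cells$humidity_df[i]
    pp <- config$sensitivity_percentiles[[cells$pct[i]]]
    cfg$p_low <- pp[1]; cfg$p_high <- pp[2]
    cfg$subgroups <- config$sensitivity_subgroups
    for (g in cfg$subgroups) {
      res <- tryCatch(.fit_subgroup(series, g, cfg),
                      error = function(e) list(subgroup = g,
                                               error = conditionMessage(e)))
      if (!is.null(res$error)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subgroup = g, max_lag = cfg$max_lag, humidity_df = cfg$humidity_df,
          p_low = pp[1], p_high = pp[2], extreme = NA, temp = NA, mmt = NA,
          or = NA, lo = NA, hi = NA, error = res$error)
        next
      }
      cum <- res$effects[res$effects$type == "cumulative" &
                           res$effects$lag == cfg$max_lag, ]
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = g, max_lag = cfg$max_lag, humidity_df = cfg$humidity_df,
        p_low = pp[1], p_high = pp[2],
        extreme = c("low", "high"), temp = cum$temp, mmt = res$mmt,
        or = cum$or, lo = cum$lo, hi = cum$hi, error = NA_character_)
    }
  }
  grid <- do.call(rbind, rows)
  out <- structure(list(grid = grid,
                        provenance = list(config = unclass(config),
                                          config_hash = .config_hash(config))),
                   class = "sensitivity_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    g2 <- grid
    g2[c("or", "lo", "hi")] <- lapply(g2[c("or", "lo", "hi")], round, 3)
    utils::write.table(g2, file.path(out_dir, "sensitivity_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  ok <- x$grid[is.na(x$grid$error), ]
  cat("Sensitivity grid:", nrow(unique(x$grid[c("max_lag", "humidity_df",
                                                "p_low")])), "cells,",
      sum(is.na(x$grid$error)) / 2, "successful fits\n")
  cat("  cumulative OR range at extremes: low",
      sprintf("%.3f-%.3f", min(ok$or[ok$extreme == "low"]),
              max(ok$or[ok$extreme == "low"])), "| high",
      sprintf("%.3f-%.3f", min(ok$or[ok$extreme == "high"]),
              max(ok$or[ok$extreme == "high"])), "\n")
  invisible(x)
}
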