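#' Configuration for a full pipeline run
#'
#' A run covers one or more geographies. Each geography supplies an RSV
#' series, an optional falsification-control series, and an environmental
#' panel — either as file paths (CSV, see [read_panel()]), as tibbles, or
#' generated synthetically from a [synth_config()]. Synthetic geographies
#' derive their seeds from the pipeline seed plus the geography index, so a
#' run is reproducible end to end from the configuration alone.
#'
#' @param geographies Named list. Each element is either a list with
#'   elements `rsv`, `panel`, and optionally `control` (paths or tibbles),
#'   or a [synth_config()] to simulate that geography.
#' @param df Spline degrees of freedom (default 4).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer master seed.
#' @param thresholds Significance tiers for the correlation screen,
#'   default `c(0.05, 0.001)`; must be strictly between 0 and 1.
#' @param alpha Trend significance threshold for the falsification verdict.
#' @param dtw_cost,dtw_normalize DTW options, see [dtw_distance()].
#' @param exact_seasonality If `TRUE`, add a permutation p-value to the
#'   seasonality test.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(geographies, df = 4, n_boot = 1000, seed = 1L,
                            thresholds = c(0.05, 0.001), alpha = 0.05,
                            dtw_cost = "abs", dtw_normalize = FALSE,
                            exact_seasonality = FALSE) {
  if (!is.list(geographies) || length(geographies) == 0 ||
      is.null(names(geographies)) || any(names(geographies) == "")) {
    abort("`geographies` must be a nonempty named list",
          class = "infotrend_config_error")
  }
  if (any(thresholds <= 0) || any(thresholds >= 1) ||
      length(thresholds) != 2 || thresholds[1] <= thresholds[2]) {
    abort("`thresholds` must be two values strictly between 0 and 1, ordered loose-to-strict",
          class = "infotrend_config_error")
  }
  structure(
    list(geographies = geographies, df = df, n_boot = as.integer(n_boot),
         seed = as.integer(seed), thresholds = thresholds, alpha = alpha,
         dtw_cost = dtw_cost, dtw_normalize = dtw_normalize,
         exact_seasonality = exact_seasonality),
    class = "pipeline_config"
  )
}

resolve_input <- function(x) {
  if (is.character(x)) read_panel(x) else tibble::as_tibble(x)
}

# Materialize one geography's inputs (load or simulate); index feeds the
# per-geography synthetic seed.
materialize_geography <- function(geo, index, config) {
  if (inherits(geo, "synth_config")) {
    geo$seed <- as.integer((config$seed + 10007 * index) %% 2147483647)
    study <- simulate_study(geo)
    list(rsv = study$rsv, control = study$control, panel = study$panel,
         truth = study$truth)
  } else {
    if (!is.list(geo) || is.null(geo$rsv) || is.null(geo$panel)) {
      abort("each geography needs `rsv` and `panel` (or a synth_config)",
            class = "infotrend_config_error")
    }
    list(
      rsv = resolve_input(geo$rsv),
      control = if (!is.null(geo$control)) resolve_input(geo$control),
      panel = resolve_input(geo$panel),
      truth = NULL
    )
  }
}

#' Run the full analysis pipeline
#'
#' For each geography, in order: trend estimation with residual-bootstrap
#' inference on MID (plus the falsification contrast when a control series
#' is present), the month-of-year Kruskal-Wallis test, panel preprocessing
#' and the Spearman correlation screen, and DTW ranking of the significant
#' parameters. All randomness derives from the configuration seed, so the
#' same configuration reproduces the same report bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages (sent to stderr).
#' @return An object of class `run_report`: per-geography results plus the
#'   configuration echo and package version.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (!quiet) inform(sprintf(fmt, ...))
  results <- list()
  for (g in seq_along(config$geographies)) {
    name <- names(config$geographies)[g]
    say("[%s] preparing inputs", name)
    geo <- materialize_geography(config$geographies[[g]], g, config)

    say("[%s] trend: spline df=%d, residual bootstrap x%d", name,
        config$df, config$n_boot)
    boot_seed <- as.integer((config$seed + 31 * g) %% 2147483647)
    target <- bootstrap_mid(geo$rsv, df = config$df, n_boot = config$n_boot,
                            seed = boot_seed)
    falsification <- NULL
    if (!is.null(geo$control)) {
      control <- bootstrap_mid(geo$control, df = config$df,
                               n_boot = config$n_boot,
                               seed = as.integer(boot_seed + 1))
      falsification <- falsification_contrast(target, control,
                                              alpha = config$alpha)
    }

    say("[%s] seasonality: Kruskal-Wallis by calendar month", name)
    season <- test_seasonality(geo$rsv, exact = config$exact_seasonality,
                               seed = as.integer(config$seed + 57 * g))

    say("[%s] correlation screen", name)
    prep <- preprocess_panel(geo$panel)
    screen <- correlate_panel(prep$panel, geo$rsv,
                              thresholds = config$thresholds)

    say("[%s] DTW alignment of %d significant parameter(s)", name,
        sum(screen$tier != "none"))
    dtw <- withCallingHandlers(
      rank_alignment(prep$panel, geo$rsv, screen,
                     cost = config$dtw_cost, normalize = config$dtw_normalize),
      message = function(m) if (quiet) invokeRestart("muffleMessage")
    )

    results[[name]] <- list(
      trend = target,
      falsification = falsification,
      seasonality = season,
      exclusions = prep$exclusions,
      correlations = screen,
      dtw = dtw,
      truth = geo$truth
    )
  }
  structure(
    list(
      version = as.character(utils::packageVersion("infotrend")),
      config = config,
      geographies = results
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d geograph%s, infotrend %s\n",
              length(x$geographies),
              if (length(x$geographies) == 1) "y" else "ies", x$version))
  for (name in names(x$geographies)) {
    r <- x$geographies[[name]]
    cat(sprintf(
      "  %s: MID %.3f (CI %.3f to %.3f, p %.3g); KW p %.3g; %d/%d params significant\n",
      name, r$trend$mid, r$trend$ci_low, r$trend$ci_high, r$trend$p_value,
      r$seasonality$p_value, sum(r$correlations$tier != "none"),
      nrow(r$correlations)))
  }
  invisible(x)
}

# Flatten a run_report into plain lists/data frames for JSON serialization.
report_payload <- function(report) {
  geo <- purrr::map(report$geographies, function(r) {
    list(
      trend = as.list(glance(r$trend)),
      derivatives = r$trend$derivatives |>
        dplyr::mutate(date = format(date, "%Y-%m")),
      falsification = if (!is.null(r$falsification)) as.list(r$falsification),
      seasonality = as.list(glance(r$seasonality)),
      monthly_summaries = r$seasonality$monthly |>
        dplyr::mutate(month = as.character(month)),
      excluded_parameters = r$exclusions,
      correlations = r$correlations,
      n_correlation_tests = attr(r$correlations, "n_tests"),
      dtw = r$dtw
    )
  })
  cfg <- unclass(report$config)
  cfg$geographies <- purrr::map(cfg$geographies, function(g) {
    if (inherits(g, "synth_config")) c(list(synthetic = TRUE), unclass(g)) else
      list(synthetic = FALSE)
  })
  list(version = report$version, seed = report$config$seed,
       config = cfg, geographies = geo)
}

#' Write a run report to disk
#'
#' Writes a pretty-printed JSON report plus flat CSV tables (one correlation
#' table and one DTW ranking per geography). The report contains no
#' timestamps or machine details, so identical configurations yield
#' byte-identical files.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_payload(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  for (name in names(report$geographies)) {
    r <- report$geographies[[name]]
    readr::write_csv(r$correlations,
                     file.path(dir, sprintf("correlations_%s.csv", name)))
    readr::write_csv(r$dtw, file.path(dir, sprintf("dtw_%s.csv", name)))
  }
  invisible(json_path)
}
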