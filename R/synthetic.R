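#' Configuration for the synthetic monthly-panel generator
#'
#' Defines a self-contained study emulating monthly relative search volume
#' (RSV, 0-100) and an environmental-parameter panel with known ground truth:
#' trend shape and size, seasonal amplitude, noise, how many environmental
#' series are monotonically linked to the RSV signal (and how strongly, with
#' what lag and sign), how many are independent noise, and the interior
#' missing-data rate.
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' 68-month window starting December 2018, a smooth nonlinear rise of about
#' 40 RSV units, no month-of-year seasonality, and a small interior
#' missing-data rate in the environmental panel.
#'
#' @param n_months Number of consecutive months (>= 24, so every calendar
#'   month appears at least twice).
#' @param start First month, `"YYYY-MM"`.
#' @param trend_kind `"none"`, `"linear"`, or `"smooth_rise"` (logistic ramp).
#' @param trend_total_rise RSV units gained over the full window.
#' @param base_level RSV level at the start of the window.
#' @param seasonal_amplitude Amplitude (RSV units) of a sinusoidal
#'   month-of-year component; 0 disables seasonality.
#' @param noise_sd Standard deviation of additive Gaussian noise, RSV units.
#' @param n_env_linked Number of environmental series sharing the RSV signal.
#' @param n_env_null Number of independent environmental series.
#' @param link_strength Fraction in `[0, 1]` of a linked series' variance
#'   contributed by the shared signal.
#' @param link_lag Integer months by which linked series lead RSV.
#' @param link_sign `+1` or `-1`, recycled across linked series.
#' @param missing_rate Fraction in `[0, 0.3]` of interior environmental cells
#'   masked as missing.
#' @param seed Integer seed; every series draws from its own stream derived
#'   from `(seed, series index)`, so adding a series never perturbs earlier
#'   ones.
#' @return An object of class `synth_config`.
#' @examples
#' synth_config(n_months = 36, trend_kind = "linear", trend_total_rise = 20)
#' @export
synth_config <- function(n_months = 68,
                         start = "2018-12",
                         trend_kind = c("smooth_rise", "linear", "none"),
                         trend_total_rise = 40,
                         base_level = 40,
                         seasonal_amplitude = 0,
                         noise_sd = 8,
                         n_env_linked = 3,
                         n_env_null = 3,
                         link_strength = 0.7,
                         link_lag = 1,
                         link_sign = 1,
                         missing_rate = 0.02,
                         seed = 1L) {
  trend_kind <- match.arg(trend_kind)
  if (!is.numeric(n_months) || n_months < 24) {
    abort("`n_months` must be >= 24 (two of each calendar month)",
          class = "infotrend_config_error")
  }
  check_range <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      abort(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
            class = "infotrend_config_error")
    }
  }
  check_range(link_strength, 0, 1, "link_strength")
  check_range(missing_rate, 0, 0.3, "missing_rate")
  if (noise_sd < 0 || seasonal_amplitude < 0) {
    abort("`noise_sd` and `seasonal_amplitude` must be nonnegative",
          class = "infotrend_config_error")
  }
  if (n_env_linked < 0 || n_env_null < 0) {
    abort("series counts must be nonnegative", class = "infotrend_config_error")
  }
  if (!all(link_sign %in% c(-1, 1))) {
    abort("`link_sign` entries must be +1 or -1", class = "infotrend_config_error")
  }
  structure(
    list(
      n_months = as.integer(n_months), start = start, trend_kind = trend_kind,
      trend_total_rise = trend_total_rise, base_level = base_level,
      seasonal_amplitude = seasonal_amplitude, noise_sd = noise_sd,
      n_env_linked = as.integer(n_env_linked), n_env_null = as.integer(n_env_null),
      link_strength = link_strength, link_lag = as.integer(link_lag),
      link_sign = rep_len(as.integer(link_sign), max(1L, as.integer(n_env_linked))),
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# one RNG substream per series; index 0 = RSV, -1 = control, 1..k = env series
series_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + (index + 2) * 30269) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Noiseless trend (pre-clip) and its exact per-month derivative at each month.
# smooth_rise is a logistic ramp centred mid-window with steepness n/6,
# normalized to rise exactly trend_total_rise over the window.
noiseless_trend <- function(config) {
  n <- config$n_months
  i <- seq_len(n)
  switch(config$trend_kind,
    none = list(level = rep(config$base_level, n), deriv = rep(0, n)),
    linear = {
      slope <- config$trend_total_rise / (n - 1)
      list(level = config$base_level + slope * (i - 1), deriv = rep(slope, n))
    },
    smooth_rise = {
      tau <- n / 6
      z <- (i - (n + 1) / 2) / tau
      g <- plogis(z)
      scale <- config$trend_total_rise / (g[n] - g[1])
      list(
        level = config$base_level + scale * (g - g[1]),
        deriv = scale * dlogis(z) / tau
      )
    }
  )
}

seasonal_component <- function(config, dates) {
  if (config$seasonal_amplitude == 0) {
    return(rep(0, length(dates)))
  }
  mo <- as.integer(format(dates, "%m"))
  config$seasonal_amplitude * sin(2 * pi * (mo - 1) / 12)
}

#' Simulate a relative-search-volume series with known trend truth
#'
#' Generates `trend + seasonality + Gaussian noise`, clipped to the RSV range
#' `[0, 100]`. Ground truth (`true_mid`, the analytic mean per-month
#' derivative of the noiseless trend) is computed on the pre-clip noiseless
#' signal, mirroring the relative normalization of search-volume exports
#' while keeping the truth analytic.
#'
#' @param config A [synth_config()].
#' @param stream_index Internal RNG stream selector (0 = RSV, -1 = control).
#' @return A list with `series` (tibble `date`, `value`) and `truth` (list
#'   with `true_mid`, the noiseless trend, and the stream seed).
#' @examples
#' sim <- simulate_rsv(synth_config(n_months = 36, seed = 7))
#' head(sim$series)
#' sim$truth$true_mid
#' @export
simulate_rsv <- function(config, stream_index = 0L) {
  stopifnot(inherits(config, "synth_config"))
  dates <- month_grid(config$start, config$n_months)
  tr <- noiseless_trend(config)
  signal <- tr$level + seasonal_component(config, dates)
  noise <- with_seed(
    series_seed(config$seed, stream_index),
    rnorm(config$n_months, 0, config$noise_sd)
  )
  value <- pmin(100, pmax(0, signal + noise))
  list(
    series = tibble::tibble(date = dates, value = value),
    truth = list(
      true_mid = mean(tr$deriv),
      noiseless = tibble::tibble(date = dates, value = tr$level),
      stream_seed = series_seed(config$seed, stream_index)
    )
  )
}

#' Simulate an environmental-parameter panel linked to an RSV signal
#'
#' Linked series are built as
#' `sign * (sqrt(link_strength) * z_shifted + sqrt(1 - link_strength) * noise)`
#' on the standardized noiseless RSV signal, shifted so the environmental
#' series leads RSV by `link_lag` months (edge months repeat), then mapped to
#' arbitrary native units. Null series are independent Gaussian noise.
#' Interior cells are masked at `missing_rate`; the first and last month of a
#' series are never masked, matching interior-only interpolation downstream.
#'
#' @param config A [synth_config()].
#' @param rsv A result of [simulate_rsv()] (its noiseless truth is used as
#'   the shared signal) or a plain monthly-series data frame.
#' @return A list with `panel` (wide tibble: `date` + one column per series,
#'   `NA` = masked) and `truth` (tibble: `parameter`, `linked`, `sign`,
#'   `lag`; plus `masked` tibble of parameter/row pairs).
#' @export
simulate_env_panel <- function(config, rsv) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_months
  if (config$n_env_linked > 0 && abs(config$link_lag) >= n / 2) {
    abort("`link_lag` must be smaller than n_months / 2",
          class = "infotrend_config_error")
  }
  signal <- if (is.list(rsv) && !is.data.frame(rsv) && !is.null(rsv$truth)) {
    rsv$truth$noiseless
  } else {
    rsv
  }
  signal <- validate_series(signal, arg = "rsv")
  if (nrow(signal) != n) {
    abort("`rsv` length must equal `n_months`", class = "infotrend_config_error")
  }
  z <- zscore(signal$value, label = "rsv signal")

  # env leads RSV by `lag`: env(t) mirrors the signal at t + lag
  lag <- config$link_lag
  idx <- pmin(n, pmax(1, seq_len(n) + lag))
  z_shift <- z[idx]

  cols <- list()
  truth <- list()
  masked <- list()
  k <- config$n_env_linked
  m <- config$n_env_null
  for (j in seq_len(k + m)) {
    linked <- j <= k
    name <- if (linked) paste0("linked_", j) else paste0("null_", j - k)
    vals <- with_seed(series_seed(config$seed, j), {
      if (linked) {
        sgn <- config$link_sign[j]
        ls <- config$link_strength
        core <- sgn * (sqrt(ls) * z_shift + sqrt(1 - ls) * rnorm(n))
        v <- 50 + 10 * core
      } else {
        v <- rnorm(n, 50, 10)
      }
      if (config$missing_rate > 0) {
        hit <- runif(n) < config$missing_rate
        hit[c(1, n)] <- FALSE
        v[hit] <- NA_real_
      }
      v
    })
    cols[[name]] <- vals
    masked[[name]] <- which(is.na(vals))
    truth[[name]] <- tibble::tibble(
      parameter = name, linked = linked,
      sign = if (linked) config$link_sign[j] else NA_integer_,
      lag = if (linked) lag else NA_integer_
    )
  }
  panel <- tibble::tibble(date = signal$date, !!!cols)
  masked_tbl <- purrr::imap_dfr(masked, function(rows, nm) {
    tibble::tibble(parameter = nm, row = rows)
  })
  list(
    panel = panel,
    truth = list(series = dplyr::bind_rows(truth), masked = masked_tbl)
  )
}

#' Simulate a complete synthetic study for one geography
#'
#' Bundles the RSV series, a flat falsification-control series (same noise
#' level, `trend_kind = "none"`, its own RNG stream), and the environmental
#' panel, with all ground truth.
#'
#' @param config A [synth_config()].
#' @return A list with `rsv`, `control`, `panel` (tibbles) and `truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rsv <- simulate_rsv(config, stream_index = 0L)
  ctrl_config <- config
  ctrl_config$trend_kind <- "none"
  ctrl_config$base_level <- config$base_level
  control <- simulate_rsv(ctrl_config, stream_index = -1L)
  env <- simulate_env_panel(config, rsv)
  list(
    rsv = rsv$series,
    control = control$series,
    panel = env$panel,
    truth = list(
      rsv = rsv$truth, control = control$truth,
      env = env$truth, config = unclass(config)
    )
  )
}

#' Write synthetic ground truth as a JSON sidecar
#'
#' @param truth The `truth` element of [simulate_study()] or
#'   [simulate_env_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
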