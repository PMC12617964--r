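#' Build a consecutive monthly date grid
#'
#' @param start First month, as `"YYYY-MM"` or a `Date`.
#' @param n_months Number of consecutive months.
#' @return A `Date` vector of length `n_months`, one first-of-month per entry.
#' @examples
#' month_grid("2018-12", 4)
#' @export
month_grid <- function(start, n_months) {
  start <- parse_year_month(start)
  seq(start, by = "month", length.out = n_months)
}

# "YYYY-MM" (or Date) -> first-of-month Date; abort with offending value
parse_year_month <- function(x, what = "start") {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  ok <- grepl("^\\d{4}-\\d{2}$", x)
  if (!all(ok)) {
    abort(sprintf(
      "%s must be 'YYYY-MM'; offending value(s): %s",
      what, paste(x[!ok], collapse = ", ")
    ), class = "infotrend_parse_error")
  }
  out <- as.Date(paste0(x, "-01"))
  if (anyNA(out)) {
    abort(sprintf(
      "unparseable year-month value(s): %s", paste(x[is.na(out)], collapse = ", ")
    ), class = "infotrend_parse_error")
  }
  out
}

#' Numeric-year time axis for monthly data
#'
#' Maps each month to `year + (calendar_month - 0.5) / 12`, the midpoint of
#' the month on a decimal-year axis. On this scale spline derivatives are in
#' units per year, so dividing an average yearly rate by 12 gives an average
#' monthly rate literally.
#'
#' @param dates A `Date` vector of first-of-month dates.
#' @return Numeric vector of decimal years.
#' @export
decimal_year <- function(dates) {
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  yr + (mo - 0.5) / 12
}

# Validate the (date, value) monthly-series contract shared by every stage:
# a data frame with a Date `date` column on a strictly consecutive monthly
# grid (no duplicates, no gaps) and a numeric `value` column, length >= 2.
validate_series <- function(data, allow_missing = FALSE,
                            arg = deparse(substitute(data))) {
  if (!is.data.frame(data) || !all(c("date", "value") %in% names(data))) {
    abort(sprintf("`%s` must be a data frame with columns `date` and `value`", arg),
          class = "infotrend_series_error")
  }
  dates <- data$date
  if (!inherits(dates, "Date")) {
    dates <- parse_year_month(as.character(dates), what = sprintf("`%s$date`", arg))
  }
  if (nrow(data) < 2) {
    abort(sprintf("`%s` must contain at least 2 months", arg),
          class = "infotrend_series_error")
  }
  if (anyDuplicated(dates)) {
    dup <- format(dates[duplicated(dates)][1], "%Y-%m")
    abort(sprintf("duplicated date in `%s`: %s", arg, dup),
          class = "infotrend_series_error")
  }
  expected <- month_grid(dates[1], length(dates))
  if (!identical(as.numeric(dates), as.numeric(expected))) {
    gaps <- format(expected[expected != dates][1], "%Y-%m")
    abort(sprintf(
      "`%s` dates must be strictly consecutive months; first mismatch near %s",
      arg, gaps
    ), class = "infotrend_series_error")
  }
  if (!is.numeric(data$value)) {
    abort(sprintf("`%s$value` must be numeric", arg), class = "infotrend_series_error")
  }
  if (!allow_missing && anyNA(data$value)) {
    abort(sprintf("`%s` contains missing values; interpolate or exclude first", arg),
          class = "infotrend_series_error")
  }
  tibble::tibble(date = dates, value = as.numeric(data$value))
}

#' Fill interior missing values by linear interpolation
#'
#' Each run of missing months strictly inside the series is filled linearly
#' between its flanking observed values; observed values are untouched. A
#' series whose first or last month is missing cannot be interpolated and is
#' rejected (panels flag such parameters as excluded instead, see
#' [preprocess_panel()]).
#'
#' @param data A monthly-series data frame with columns `date`, `value`
#'   (`NA` = missing).
#' @return A tibble with the same dates and all `NA` runs filled.
#' @examples
#' x <- tibble::tibble(date = month_grid("2020-01", 3), value = c(1, NA, 3))
#' interpolate_missing(x)
#' @export
interpolate_missing <- function(data) {
  s <- validate_series(data, allow_missing = TRUE)
  v <- s$value
  if (!anyNA(v)) {
    return(s)
  }
  if (is.na(v[1]) || is.na(v[length(v)])) {
    abort("leading or trailing month is missing; series cannot be interpolated",
          class = "infotrend_edge_missing")
  }
  s$value <- as.numeric(zoo::na.approx(v, x = seq_along(v)))
  s
}

#' Standardize a monthly series to zero mean and unit variance
#'
#' Uses the sample standard deviation (divisor n - 1). Rank-based statistics
#' downstream (Spearman, and DTW on already-standardized inputs) are invariant
#' or insensitive to this affine transform; it is applied for comparability of
#' DTW costs across parameters with different native units.
#'
#' @param data A monthly-series data frame (`date`, `value`), no missing values.
#' @return A tibble with `value` standardized.
#' @export
standardize <- function(data) {
  s <- validate_series(data)
  s$value <- zscore(s$value)
  s
}

# vector z-score; aborts on zero variance
zscore <- function(v, label = "series") {
  stopifnot(is.numeric(v), !anyNA(v))
  sdev <- sd(v)
  if (!is.finite(sdev) || sdev == 0) {
    abort(sprintf("cannot standardize constant %s (zero variance)", label),
          class = "infotrend_constant_series")
  }
  (v - mean(v)) / sdev
}
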