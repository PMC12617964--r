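#' Read a monthly panel or series from CSV
#'
#' Expects a `date` column in ISO `YYYY-MM` plus at least one numeric value
#' column. Validates the month grid strictly: dates must parse, be unique,
#' and form a consecutive monthly sequence; empty cells become missing
#' values.
#'
#' @param path Path to a CSV file.
#' @return A wide tibble: `date` (`Date`, first of month) plus one numeric
#'   column per variable.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "infotrend_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_character(), .default = readr::col_double()
  ))
  if (!"date" %in% names(raw) || ncol(raw) < 2) {
    abort("CSV must have a `date` column plus at least one value column",
          class = "infotrend_io_error")
  }
  bad <- which(!grepl("^\\d{4}-\\d{2}$", raw$date))
  if (length(bad) > 0) {
    abort(sprintf("unparseable date at row %d: '%s' (expected YYYY-MM)",
                  bad[1], raw$date[bad[1]]),
          class = "infotrend_io_error")
  }
  dates <- parse_year_month(raw$date)
  if (anyDuplicated(dates)) {
    abort(sprintf("duplicated date: %s",
                  format(dates[duplicated(dates)][1], "%Y-%m")),
          class = "infotrend_io_error")
  }
  if (is.unsorted(dates)) {
    ord <- order(dates)
    dates <- dates[ord]
    raw <- raw[ord, ]
  }
  expected <- month_grid(dates[1], 1 + 12 * (as.integer(format(max(dates), "%Y")) -
                                               as.integer(format(dates[1], "%Y"))) +
                           as.integer(format(max(dates), "%m")) -
                           as.integer(format(dates[1], "%m")))
  if (length(expected) != length(dates)) {
    gaps <- format(expected[!expected %in% dates], "%Y-%m")
    abort(sprintf("non-consecutive months; missing: %s",
                  paste(gaps, collapse = ", ")),
          class = "infotrend_io_error")
  }
  dplyr::bind_cols(tibble::tibble(date = dates), raw[setdiff(names(raw), "date")])
}

#' Write a monthly panel or series to CSV
#'
#' Inverse of [read_panel()]: dates are written as `YYYY-MM` and missing
#' cells as empty strings, so a write-then-read round trip reproduces the
#' panel including its missing mask.
#'
#' @param data A wide tibble with a `date` column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  out <- dplyr::mutate(data, date = format(date, "%Y-%m"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
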