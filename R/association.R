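#' Preprocess an environmental panel for correlation screening
#'
#' Applies the screening pipeline's missing-data policy to every parameter
#' column of a wide panel: a parameter is excluded (with a machine-readable
#' reason) when its first or last month is missing (`edge-missing`) or when
#' more than `max_missing` of its cells are missing (`excessive-missingness`);
#' otherwise interior gaps are filled by linear interpolation between the
#' flanking observed months.
#'
#' @param panel A wide tibble: `date` column plus one numeric column per
#'   environmental parameter; `NA` marks missing cells.
#' @param max_missing Maximum tolerated fraction of missing cells
#'   (default 0.3).
#' @return A list with `panel` (the retained, interpolated columns) and
#'   `exclusions` (tibble: `parameter`, `reason`).
#' @export
preprocess_panel <- function(panel, max_missing = 0.3) {
  params <- panel_parameters(panel)
  dates <- parse_year_month(panel$date)
  keep <- list(date = dates)
  excl <- list()
  for (p in params) {
    v <- panel[[p]]
    if (is.na(v[1]) || is.na(v[length(v)])) {
      excl[[p]] <- "edge-missing"
    } else if (mean(is.na(v)) > max_missing) {
      excl[[p]] <- "excessive-missingness"
    } else {
      keep[[p]] <- interpolate_missing(tibble::tibble(date = dates, value = v))$value
    }
  }
  list(
    panel = tibble::as_tibble(keep),
    exclusions = tibble::tibble(
      parameter = names(excl),
      reason = unlist(excl, use.names = FALSE) %||% character(0)
    )
  )
}

panel_parameters <- function(panel) {
  if (!is.data.frame(panel) || !"date" %in% names(panel)) {
    abort("panel must be a data frame with a `date` column",
          class = "infotrend_panel_error")
  }
  setdiff(names(panel), "date")
}

#' Spearman rank correlation between two monthly series
#'
#' rho is the Pearson correlation of average (midrank) ranks; the two-sided
#' p-value uses the t approximation `t = rho * sqrt((n - 2)/(1 - rho^2))` on
#' `n - 2` degrees of freedom. For a perfect monotone association
#' (`|rho| = 1`) the p-value is reported at the positive floor of the
#' approximation rather than exactly zero. The significance tier reproduces
#' the two-star reporting convention: `p<.001`, `p<.05`, or `none`.
#'
#' @param x,y Numeric vectors or monthly-series data frames of equal length
#'   (>= 5), no missing values.
#' @param thresholds The two tier thresholds, default `c(0.05, 0.001)`.
#' @param parameter Optional label for the record.
#' @return A one-row tibble: `parameter`, `rho`, `p_value`, `tier`,
#'   `n_effective`.
#' @examples
#' spearman_cor(1:10, exp(1:10))  # rho = 1: monotone invariance
#' @export
spearman_cor <- function(x, y, thresholds = c(0.05, 0.001), parameter = NA_character_) {
  xv <- series_values(x)
  yv <- series_values(y)
  if (length(xv) != length(yv)) {
    abort("series must have equal length", class = "infotrend_cor_error")
  }
  n <- length(xv)
  if (n < 5) {
    abort("need at least 5 paired months for the correlation screen",
          class = "infotrend_cor_error")
  }
  if (anyNA(xv) || anyNA(yv)) {
    abort("missing values present; interpolate or exclude first",
          class = "infotrend_cor_error")
  }
  rx <- rank(xv)
  ry <- rank(yv)
  # perfect monotone (dis)cordance is exact by definition; cor()'s floating
  # arithmetic would return 1 - 2e-16 here
  rho <- if (all(rx == ry)) 1 else if (all(rx == n + 1 - ry)) -1 else cor(rx, ry)
  if (is.na(rho)) {
    abort("rho undefined: one input is constant after ranking",
          class = "infotrend_cor_error")
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p <- max(p, .Machine$double.xmin)
  tibble::tibble(
    parameter = parameter, rho = rho, p_value = p,
    tier = p_tier(p, thresholds), n_effective = n
  )
}

series_values <- function(x) {
  if (is.data.frame(x)) validate_series(x, allow_missing = TRUE)$value else as.numeric(x)
}

p_tier <- function(p, thresholds = c(0.05, 0.001)) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  dplyr::case_when(
    p < thresholds[2] ~ sprintf("p<%s", sub("^0", "", format(thresholds[2]))),
    p < thresholds[1] ~ sprintf("p<%s", sub("^0", "", format(thresholds[1]))),
    .default = "none"
  )
}

#' Correlation screen of an environmental panel against an RSV series
#'
#' Runs [spearman_cor()] for every retained parameter of a preprocessed
#' panel, in the panel's column order (conventionally meteorological
#' parameters first, then pollutants), with no multiplicity adjustment —
#' the number of tests performed is attached so readers can apply their own
#' correction.
#'
#' @param panel A preprocessed wide panel (no missing cells), e.g. the
#'   `panel` element of [preprocess_panel()].
#' @param rsv The RSV monthly-series data frame on the same date grid.
#' @param thresholds Tier thresholds, default `c(0.05, 0.001)`.
#' @return A tibble with one row per parameter (`parameter`, `rho`,
#'   `p_value`, `tier`, `n_effective`), attribute `n_tests`.
#' @export
correlate_panel <- function(panel, rsv, thresholds = c(0.05, 0.001)) {
  params <- panel_parameters(panel)
  if (length(params) == 0) {
    abort("panel contains no parameter columns", class = "infotrend_panel_error")
  }
  rsv_s <- validate_series(rsv, arg = "rsv")
  if (nrow(rsv_s) != nrow(panel)) {
    abort("rsv and panel must cover the same months", class = "infotrend_panel_error")
  }
  out <- purrr::map(params, function(p) {
    spearman_cor(rsv_s$value, panel[[p]], thresholds = thresholds, parameter = p)
  }) |> dplyr::bind_rows()
  attr(out, "n_tests") <- length(params)
  out
}

#' Lollipop chart of a correlation screen
#'
#' @param screen Output of [correlate_panel()].
#' @return A ggplot object: rho per parameter, coloured by significance tier.
#' @export
plot_correlation_screen <- function(screen) {
  screen <- dplyr::mutate(screen,
                          parameter = factor(parameter, levels = rev(parameter)))
  ggplot2::ggplot(screen, ggplot2::aes(x = rho, y = parameter, colour = tier)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = rho, yend = parameter),
                          linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Spearman rho vs RSV", y = NULL, colour = "tier") +
    ggplot2::theme_minimal()
}
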