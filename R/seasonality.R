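#' Tie-corrected Kruskal-Wallis test with an all-ties convention
#'
#' The computational kernel behind [test_seasonality()], usable on any
#' grouping. Returns the tie-corrected H statistic with its chi-square
#' p-value on `k - 1` degrees of freedom; when every value is tied the tie
#' correction degenerates and the result is reported as `H = 0`, `p = 1`.
#' Optionally adds a Monte-Carlo permutation p-value,
#' `(1 + #\{H* >= H\}) / (n_perm + 1)`.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (or coercible), same length.
#' @param exact If `TRUE`, also compute the permutation p-value.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draw.
#' @return A list: `h_statistic`, `dof`, `p_value`, `p_permutation`
#'   (`NULL` unless `exact`).
#' @export
kruskal_wallis <- function(values, groups, exact = FALSE, n_perm = 2000,
                           seed = 1L) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  g <- droplevels(as.factor(groups))
  if (length(unique(values)) == 1) {
    return(list(h_statistic = 0, dof = nlevels(g) - 1L, p_value = 1,
                p_permutation = NULL))
  }
  kt <- kruskal.test(values, g)
  out <- list(h_statistic = unname(kt$statistic),
              dof = unname(kt$parameter),
              p_value = kt$p.value,
              p_permutation = NULL)
  if (exact) {
    h_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        unname(kruskal.test(sample(values), g)$statistic)
      }, numeric(1))
    })
    out$p_permutation <- (1 + sum(h_perm >= out$h_statistic)) / (n_perm + 1)
  }
  out
}

#' Month-of-year seasonality test (Kruskal-Wallis)
#'
#' Groups a monthly series by calendar month and tests for location
#' differences with the tie-corrected Kruskal-Wallis test; the p-value comes
#' from the chi-square approximation with `k - 1` degrees of freedom. An
#' optional Monte-Carlo permutation p-value is available for small samples
#' where the chi-square approximation is marginal. When every value is tied
#' the statistic degenerates and is reported as `H = 0`, `p = 1`.
#'
#' @param data A complete monthly-series data frame covering each calendar
#'   month at least twice.
#' @param exact If `TRUE`, also compute a Monte-Carlo permutation p-value.
#' @param n_perm Number of permutations when `exact = TRUE`.
#' @param seed Seed for the permutation draw.
#' @return An object of class `seasonality_test`: `h_statistic`, `dof`,
#'   `p_value` (chi-square), optional `p_permutation`, and a `monthly`
#'   tibble of per-month summaries (n, median, quartiles, min, max).
#' @examples
#' sim <- simulate_rsv(synth_config(n_months = 48, seed = 5))
#' test_seasonality(sim$series)
#' @export
test_seasonality <- function(data, exact = FALSE, n_perm = 2000, seed = 1L) {
  s <- validate_series(data)
  month_num <- as.integer(format(s$date, "%m"))
  g <- factor(month.abb[month_num], levels = month.abb[sort(unique(month_num))])
  counts <- table(g)
  if (any(counts < 2)) {
    bad <- names(counts)[counts < 2]
    abort(sprintf("calendar month(s) with fewer than 2 observations: %s",
                  paste(bad, collapse = ", ")),
          class = "infotrend_seasonality_error")
  }
  kw <- kruskal_wallis(s$value, g, exact = exact, n_perm = n_perm, seed = seed)
  monthly <- s |>
    dplyr::mutate(month = g) |>
    dplyr::group_by(month) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(value),
      q1 = unname(quantile(value, 0.25)),
      q3 = unname(quantile(value, 0.75)),
      min = min(value),
      max = max(value),
      .groups = "drop"
    )
  structure(
    list(h_statistic = kw$h_statistic, dof = kw$dof, p_value = kw$p_value,
         p_permutation = kw$p_permutation,
         monthly = monthly, data = s |> dplyr::mutate(month = g)),
    class = "seasonality_test"
  )
}

#' @export
print.seasonality_test <- function(x, ...) {
  cat(sprintf("<seasonality_test> Kruskal-Wallis H = %.3f, df = %d, p = %.3g\n",
              x$h_statistic, x$dof, x$p_value))
  if (!is.null(x$p_permutation)) {
    cat(sprintf("  permutation p = %.3g\n", x$p_permutation))
  }
  invisible(x)
}

#' @rdname test_seasonality
#' @param x A `seasonality_test`.
#' @param ... Unused.
#' @method tidy seasonality_test
#' @export
tidy.seasonality_test <- function(x, ...) {
  x$monthly
}

#' @rdname test_seasonality
#' @method glance seasonality_test
#' @export
glance.seasonality_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$h_statistic, df = x$dof, p.value = x$p_value,
    p.permutation = x$p_permutation %||% NA_real_
  )
}
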