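#' @rdname fit_trend
#' @param object A `trend_fit`.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  curve <- tibble::tibble(
    date = object$data$date,
    fitted = object$fitted
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = date, y = value)) +
    ggplot2::geom_point(colour = "grey35", size = 1.4) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = fitted),
                       colour = "#2171b5", linewidth = 0.9) +
    ggplot2::labs(x = NULL, y = "relative search volume",
                  subtitle = if (object$r_squared_defined) {
                    sprintf("spline df = %d, adjusted R² = %.3f",
                            object$df, object$adj_r_squared)
                  } else {
                    sprintf("spline df = %d", object$df)
                  }) +
    ggplot2::theme_minimal()
}

#' @rdname bootstrap_mid
#' @param object A `trend_estimate`.
#' @method autoplot trend_estimate
#' @export
autoplot.trend_estimate <- function(object, ...) {
  autoplot(object$fit) +
    ggplot2::labs(title = sprintf(
      "MID = %.3f per month (%d%% CI %.3f to %.3f, p = %.3g)",
      object$mid, round(100 * object$level),
      object$ci_low, object$ci_high, object$p_value))
}

#' @rdname test_seasonality
#' @param object A `seasonality_test`.
#' @method autoplot seasonality_test
#' @export
autoplot.seasonality_test <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = month, y = value)) +
    ggplot2::geom_boxplot(fill = "#c6dbef", outlier.size = 1) +
    ggplot2::labs(x = NULL, y = "relative search volume",
                  subtitle = sprintf("Kruskal-Wallis H = %.2f, p = %.2g",
                                     object$h_statistic, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @rdname dtw_distance
#' @param object A `dtw_alignment`.
#' @param ... Unused.
#' @method autoplot dtw_alignment
#' @export
autoplot.dtw_alignment <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = i, y = j)) +
    ggplot2::geom_path(colour = "#2171b5") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "RSV month index", y = "parameter month index",
                  subtitle = sprintf("DTW distance = %.3f", object$distance)) +
    ggplot2::theme_minimal()
}
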