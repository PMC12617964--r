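#' B-spline basis for a monthly date grid
#'
#' Builds the cubic B-spline basis of the numeric-year time axis used by the
#' trend model: `df` columns excluding the constant (the intercept is a
#' separate model term), boundary knots at the first and last month, and
#' `df - degree` interior knots at quantiles of the observation times (one
#' knot at the median for the default `df = 4`).
#'
#' @param dates A `Date` vector of consecutive first-of-month dates.
#' @param df Number of spline columns (default 4).
#' @param degree Polynomial degree (default 3, cubic).
#' @return A basis matrix (rows = months) with `knots`, `Boundary.knots` and
#'   `degree` attributes, as produced by [splines::bs()].
#' @export
spline_basis <- function(dates, df = 4, degree = 3) {
  if (df < degree + 1) {
    abort(sprintf("`df` must be >= degree + 1 (= %d)", degree + 1),
          class = "infotrend_fit_error")
  }
  if (length(dates) <= df + 1) {
    abort(sprintf("need more than %d time points to fit a df=%d spline",
                  df + 1, df),
          class = "infotrend_fit_error")
  }
  splines::bs(decimal_year(dates), df = df, degree = degree)
}

# Full (clamped) knot vector of the basis, for derivative evaluation.
full_knots <- function(basis) {
  degree <- attr(basis, "degree")
  c(rep(attr(basis, "Boundary.knots")[1], degree + 1),
    attr(basis, "knots"),
    rep(attr(basis, "Boundary.knots")[2], degree + 1))
}

# Evaluate the basis (or its deriv-th derivative) at numeric-year times t.
# The intercept-carrying first column of the full basis is dropped to match
# the bs() convention. Errors outside the boundary knots.
eval_basis <- function(basis, t, deriv = 0) {
  bk <- attr(basis, "Boundary.knots")
  if (any(t < bk[1] - 1e-12 | t > bk[2] + 1e-12)) {
    abort("evaluation outside the spline's boundary knots",
          class = "infotrend_domain_error")
  }
  ord <- attr(basis, "degree") + 1
  splines::splineDesign(full_knots(basis), pmin(pmax(t, bk[1]), bk[2]),
                        ord = ord, derivs = rep(deriv, length(t)))[, -1, drop = FALSE]
}

#' Fit the spline trend model to a monthly series
#'
#' Ordinary least squares of the series values on an intercept plus the
#' `df`-column B-spline basis of decimal-year time. Reports the adjusted R²,
#' `1 - (1 - R²)(n - 1)/(n - p - 1)` with `p` the number of basis columns.
#' For a zero-variance response the fit is returned with R² flagged
#' undefined rather than propagating `NaN`.
#'
#' @param data A monthly-series data frame (`date`, `value`), complete (no
#'   missing values).
#' @param df Spline degrees of freedom (basis columns), default 4.
#' @param degree Spline degree, default 3.
#' @return An object of class `trend_fit`: coefficients, fitted values,
#'   residuals, the basis, adjusted R², and the data.
#' @examples
#' sim <- simulate_rsv(synth_config(n_months = 36, seed = 2))
#' fit <- fit_trend(sim$series)
#' glance(fit)
#' @export
fit_trend <- function(data, df = 4, degree = 3) {
  s <- validate_series(data)
  basis <- spline_basis(s$date, df = df, degree = degree)
  X <- cbind(`(Intercept)` = 1, unclass(basis)[, , drop = FALSE])
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, s$value)
  fit_vals <- drop(X %*% beta)
  res <- s$value - fit_vals
  n <- nrow(s)
  p <- ncol(basis)
  tss <- sum((s$value - mean(s$value))^2)
  r2_defined <- tss > 0
  r2 <- if (r2_defined) 1 - sum(res^2) / tss else NA_real_
  adj_r2 <- if (r2_defined) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  structure(
    list(
      coefficients = beta, fitted = fit_vals, residuals = res,
      basis = basis, qr = qr_x, data = s, t = decimal_year(s$date),
      df = df, degree = degree, n = n,
      r_squared = r2, adj_r_squared = adj_r2, r_squared_defined = r2_defined
    ),
    class = "trend_fit"
  )
}

#' Evaluate a fitted trend (or its derivative) at arbitrary times
#'
#' @param fit A `trend_fit`.
#' @param t Numeric-year times within the fitted range.
#' @param deriv Derivative order (0 = the fitted curve, 1 = yearly rate).
#' @return Numeric vector of spline values (the intercept contributes only
#'   at `deriv = 0`).
#' @export
eval_trend <- function(fit, t, deriv = 0) {
  stopifnot(inherits(fit, "trend_fit"))
  B <- eval_basis(fit$basis, t, deriv = deriv)
  out <- drop(B %*% fit$coefficients[-1])
  if (deriv == 0) out <- out + fit$coefficients[1]
  out
}

#' Instantaneous derivatives of the fitted trend at each month
#'
#' The analytic first derivative of the fitted spline (differentiated basis
#' times coefficients) evaluated at every observed month, on the decimal-year
#' axis — units are response units per year.
#'
#' @param fit A `trend_fit`.
#' @return A tibble with columns `date` and `derivative` (per year).
#' @export
trend_derivatives <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  tibble::tibble(date = fit$data$date,
                 derivative = eval_trend(fit, fit$t, deriv = 1))
}

#' Mean instantaneous derivative (MID) of a fitted trend
#'
#' The arithmetic mean of the per-month yearly derivatives, divided by 12 to
#' express the average change in response units per month. A positive MID
#' indicates an overall increasing trend.
#'
#' @param fit A `trend_fit`.
#' @return A single number, response units per month.
#' @export
trend_mid <- function(fit) {
  mean(trend_derivatives(fit)$derivative) / 12
}

#' Residual-bootstrap inference for the MID statistic
#'
#' Resamples the fit's residuals with replacement, adds them to the fitted
#' values, refits the spline model, and recomputes MID, `n_boot` times. The
#' 95% CI is the 2.5/97.5 percentile interval of the bootstrap MIDs; the
#' two-sided p-value is `2 * min(prop(MID* <= 0), prop(MID* >= 0))`, floored
#' at `2 / (n_boot + 1)`.
#'
#' @param data A complete monthly-series data frame.
#' @param df,degree Spline settings, as in [fit_trend()].
#' @param n_boot Bootstrap iterations (default 1000; fewer than 100 draws a
#'   warning, fewer than 2 is an error).
#' @param seed Integer seed; the estimate is deterministic given the seed.
#' @param level Confidence level (default 0.95).
#' @param leverage_adjust If `TRUE`, residuals are inflated by
#'   `1/sqrt(1 - h)` before resampling; default `FALSE` (raw residuals).
#' @return An object of class `trend_estimate` with elements `mid`, `ci_low`,
#'   `ci_high`, `p_value`, `n_boot`, `seed`, per-month `derivatives`,
#'   `adj_r_squared`, the underlying `fit`, and the bootstrap draws
#'   `boot_mids`.
#' @examples
#' sim <- simulate_rsv(synth_config(n_months = 36, seed = 3))
#' est <- bootstrap_mid(sim$series, n_boot = 200, seed = 1)
#' tidy(est)
#' @export
bootstrap_mid <- function(data, df = 4, degree = 3, n_boot = 1000, seed = 1L,
                          level = 0.95, leverage_adjust = FALSE) {
  if (n_boot < 2) {
    abort("`n_boot` must be at least 2", class = "infotrend_config_error")
  }
  if (n_boot < 100) {
    warn(sprintf("n_boot = %d is small; CIs and p-values will be coarse", n_boot))
  }
  fit <- fit_trend(data, df = df, degree = degree)
  n <- fit$n
  res <- fit$residuals
  if (leverage_adjust) {
    h <- rowSums(qr.Q(fit$qr)^2)
    res <- res / sqrt(pmax(1 - h, .Machine$double.eps))
  }
  d_basis <- eval_basis(fit$basis, fit$t, deriv = 1)
  boot_mids <- with_seed(seed, {
    estar <- matrix(sample(res, n * n_boot, replace = TRUE), n, n_boot)
    ystar <- fit$fitted + estar
    bstar <- qr.coef(fit$qr, ystar)
    colMeans(d_basis %*% bstar[-1, , drop = FALSE]) / 12
  })
  alpha <- 1 - level
  ci <- unname(quantile(boot_mids, c(alpha / 2, 1 - alpha / 2)))
  p <- 2 * min(mean(boot_mids <= 0), mean(boot_mids >= 0))
  p <- min(1, max(p, 2 / (n_boot + 1)))
  structure(
    list(
      mid = trend_mid(fit),
      derivatives = trend_derivatives(fit),
      ci_low = ci[1], ci_high = ci[2], p_value = p,
      n_boot = as.integer(n_boot), seed = as.integer(seed), level = level,
      df = df, degree = degree,
      adj_r_squared = fit$adj_r_squared,
      fit = fit, boot_mids = boot_mids
    ),
    class = "trend_estimate"
  )
}

#' Falsification-outcome contrast
#'
#' Juxtaposes the trend estimate for the outcome of interest with that of a
#' negative-control series expected to show no trend (e.g. search interest
#' in an unrelated common disease). A significant target alongside a
#' nonsignificant control supports a target-specific trend; a significant
#' control signals possible confounding. No new statistic is computed.
#'
#' @param target,control `trend_estimate` objects fitted with identical
#'   spline settings and bootstrap size.
#' @param alpha Significance threshold (default 0.05).
#' @return A one-row tibble: the two p-values, significance flags, and a
#'   `verdict` string.
#' @export
falsification_contrast <- function(target, control, alpha = 0.05) {
  stopifnot(inherits(target, "trend_estimate"), inherits(control, "trend_estimate"))
  if (target$df != control$df || target$degree != control$degree ||
      target$n_boot != control$n_boot) {
    abort("target and control must use identical spline df/degree and n_boot",
          class = "infotrend_config_error")
  }
  t_sig <- target$p_value < alpha
  c_sig <- control$p_value < alpha
  verdict <- if (t_sig && !c_sig) {
    "trend specific to target"
  } else if (!t_sig && !c_sig) {
    "no specific trend"
  } else if (t_sig && c_sig) {
    "nonspecific rise; confounding not excluded"
  } else {
    "control trend only; target shows no trend"
  }
  tibble::tibble(
    target_mid = target$mid, target_p = target$p_value,
    control_mid = control$mid, control_p = control$p_value,
    alpha = alpha,
    target_significant = t_sig, control_significant = c_sig,
    verdict = verdict
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> spline df=%d degree=%d on %d months\n",
              x$df, x$degree, x$n))
  if (x$r_squared_defined) {
    cat(sprintf("  adjusted R-squared: %.3f\n", x$adj_r_squared))
  } else {
    cat("  adjusted R-squared: undefined (zero-variance response)\n")
  }
  invisible(x)
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf(
    "<trend_estimate> MID = %.4g per month (%d%% CI %.4g to %.4g), p = %.3g\n",
    x$mid, round(100 * x$level), x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  residual bootstrap, %d iterations, seed %d\n", x$n_boot, x$seed))
  invisible(x)
}

#' @rdname fit_trend
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_trend
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, adj.r.squared = x$adj_r_squared,
    df = x$df, nobs = x$n
  )
}

#' @rdname bootstrap_mid
#' @param x A `trend_estimate`.
#' @param ... Unused.
#' @method tidy trend_estimate
#' @export
tidy.trend_estimate <- function(x, ...) {
  tibble::tibble(
    term = "mid", estimate = x$mid,
    conf.low = x$ci_low, conf.high = x$ci_high, p.value = x$p_value
  )
}

#' @rdname bootstrap_mid
#' @method glance trend_estimate
#' @export
glance.trend_estimate <- function(x, ...) {
  tibble::tibble(
    mid = x$mid, conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p_value, adj.r.squared = x$adj_r_squared,
    n.boot = x$n_boot, nobs = x$fit$n
  )
}
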