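test_that("spline basis: partition of unity, knot count, and domain contract", {
  dates <- month_grid("2018-12", 68)
  B <- spline_basis(dates, df = 4, degree = 3)
  # the intercept-augmented spline space sums to one everywhere on the range
  full <- splines::splineDesign(infotrend:::full_knots(B), decimal_year(dates),
                                ord = 4)
  expect_true(all(abs(rowSums(full) - 1) < 1e-10))
  expect_true(all(B >= 0 & B <= 1))
  expect_length(attr(B, "knots"), 1)  # df - degree interior knots
  expect_equal(unname(attr(B, "knots")), median(decimal_year(dates)))

  fit <- fit_trend(tibble::tibble(date = dates, value = rnorm(68)))
  expect_error(eval_trend(fit, max(decimal_year(dates)) + 0.1),
               class = "infotrend_domain_error")
  expect_error(spline_basis(month_grid("2020-01", 5), df = 4),
               class = "infotrend_fit_error")
  expect_error(spline_basis(dates, df = 3, degree = 3),
               class = "infotrend_fit_error")
})

test_that("exactly linear series are recovered exactly: fit, derivatives, MID", {
  slope_m <- 0.31
  s <- linear_series(n = 40, slope_per_month = slope_m)
  fit <- fit_trend(s)
  expect_equal(fit$fitted, s$value, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  d <- trend_derivatives(fit)$derivative
  expect_equal(d, rep(slope_m * 12, 40), tolerance = 1e-8)
  expect_equal(trend_mid(fit), slope_m, tolerance = 1e-8)
})

test_that("fit coefficients agree with an independent normal-equations solve", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(30:90, 1)
    s <- tibble::tibble(date = month_grid("2018-12", n),
                        value = rnorm(n, 50, 10))
    fit <- fit_trend(s)
    X <- cbind(1, unclass(fit$basis))
    expect_equal(unname(fit$coefficients), oracle_ols(X, s$value),
                 tolerance = 1e-6)
  }
})

test_that("analytic spline derivative matches a central-difference oracle", {
  set.seed(7)
  sim <- simulate_rsv(synth_config(seed = 7))
  fit <- fit_trend(sim$series)
  h <- 1e-5
  t_in <- fit$t[3:(fit$n - 2)]  # keep the stencil inside the boundary knots
  numeric_d <- (eval_trend(fit, t_in + h) - eval_trend(fit, t_in - h)) / (2 * h)
  analytic_d <- eval_trend(fit, t_in, deriv = 1)
  expect_equal(analytic_d, numeric_d, tolerance = 1e-4)
})

test_that("constant series: zero derivatives and an undefined R-squared flag", {
  s <- tibble::tibble(date = month_grid("2019-01", 30), value = rep(42, 30))
  fit <- fit_trend(s)
  expect_false(fit$r_squared_defined)
  expect_true(is.na(fit$adj_r_squared))
  expect_equal(trend_derivatives(fit)$derivative, rep(0, 30), tolerance = 1e-8)
})

test_that("time reversal negates MID and positive scaling scales it exactly", {
  sim <- simulate_rsv(synth_config(seed = 9))
  s <- sim$series
  mid <- trend_mid(fit_trend(s))
  rev_s <- tibble::tibble(date = s$date, value = rev(s$value))
  expect_equal(trend_mid(fit_trend(rev_s)), -mid, tolerance = 1e-8)
  scaled <- tibble::tibble(date = s$date, value = 3.7 * s$value)
  expect_equal(trend_mid(fit_trend(scaled)), 3.7 * mid, tolerance = 1e-10)
})

test_that("bootstrap on a noiseless series collapses: zero-width CI, floored p", {
  s <- linear_series(n = 36, slope_per_month = 0.4)
  est <- bootstrap_mid(s, n_boot = 500, seed = 1)
  expect_equal(est$ci_low, est$ci_high, tolerance = 1e-10)
  expect_equal(est$ci_low, est$mid, tolerance = 1e-8)
  expect_equal(est$p_value, 2 / 501)
})

test_that("bootstrap estimate is deterministic given the seed", {
  sim <- simulate_rsv(synth_config(seed = 12))
  a <- bootstrap_mid(sim$series, n_boot = 300, seed = 4)
  b <- bootstrap_mid(sim$series, n_boot = 300, seed = 4)
  expect_identical(a$boot_mids, b$boot_mids)
  expect_identical(glance(a), glance(b))
  expect_true(a$ci_low <= a$ci_high)
})

test_that("bootstrap guards: tiny n_boot errors, small n_boot warns", {
  s <- linear_series(n = 30, noise_sd = 1)
  expect_error(bootstrap_mid(s, n_boot = 1), class = "infotrend_config_error")
  expect_warning(bootstrap_mid(s, n_boot = 50, seed = 1), "small")
})

test_that("falsification contrast applies the verdict rules", {
  set.seed(3)
  target <- bootstrap_mid(linear_series(n = 36, slope_per_month = 0.8,
                                        noise_sd = 2),
                          n_boot = 200, seed = 1)
  control <- bootstrap_mid(linear_series(n = 36, slope_per_month = 0,
                                         noise_sd = 2),
                           n_boot = 200, seed = 2)
  res <- falsification_contrast(target, control)
  expect_identical(res$verdict, "trend specific to target")

  # rule application on the remaining p-value configurations
  both_null <- falsification_contrast(control, control)
  expect_identical(both_null$verdict, "no specific trend")
  both_sig <- falsification_contrast(target, target)
  expect_identical(both_sig$verdict, "nonspecific rise; confounding not excluded")

  mismatched <- bootstrap_mid(linear_series(n = 36, noise_sd = 2),
                              n_boot = 100, seed = 1)
  expect_error(falsification_contrast(target, mismatched),
               class = "infotrend_config_error")
})

test_that("tidy and glance expose the fit and estimate in standard form", {
  sim <- simulate_rsv(synth_config(seed = 21))
  fit <- fit_trend(sim$series)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 5)  # intercept + 4 basis columns
  est <- bootstrap_mid(sim$series, n_boot = 200, seed = 5)
  g <- glance(est)
  expect_named(g, c("mid", "conf.low", "conf.high", "p.value",
                    "adj.r.squared", "n.boot", "nobs"))
  expect_identical(g$mid, est$mid)
})
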