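test_that("interior gaps are filled on the line through their flanking values", {
  g3 <- month_grid("2021-01", 3)
  expect_equal(
    interpolate_missing(tibble::tibble(date = g3, value = c(1, NA, 3)))$value,
    c(1, 2, 3)
  )
  g4 <- month_grid("2021-01", 4)
  expect_equal(
    interpolate_missing(tibble::tibble(date = g4, value = c(0, NA, NA, 3)))$value,
    c(0, 1, 2, 3)
  )
  complete <- tibble::tibble(date = g4, value = c(4, 2, 7, 1))
  expect_identical(interpolate_missing(complete), complete)
  expect_error(
    interpolate_missing(tibble::tibble(date = g3, value = c(NA, 2, 3))),
    class = "infotrend_edge_missing"
  )
})

test_that("standardize gives mean 0 / sd 1, is idempotent and affine-invariant", {
  set.seed(2)
  s <- tibble::tibble(date = month_grid("2019-06", 40), value = rnorm(40, 30, 4))
  z <- standardize(s)
  expect_equal(mean(z$value), 0, tolerance = 1e-10)
  expect_equal(sd(z$value), 1, tolerance = 1e-10)
  expect_equal(standardize(z)$value, z$value, tolerance = 1e-10)
  affine <- dplyr::mutate(s, value = 5 + 2.5 * value)
  expect_equal(standardize(affine)$value, z$value, tolerance = 1e-10)
  expect_error(standardize(dplyr::mutate(s, value = 9)),
               class = "infotrend_constant_series")
})

test_that("Spearman: monotone invariance, sign, and a positive p at |rho| = 1", {
  x <- 1:10
  up <- spearman_cor(x, exp(x))
  expect_identical(up$rho, 1)
  expect_gt(up$p_value, 0)
  down <- spearman_cor(x, -x)
  expect_identical(down$rho, -1)
  set.seed(8)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(exp(a), b^3 + b)$rho,
               tolerance = 1e-12)
})

test_that("tied data reproduce the average-rank Pearson oracle", {
  x <- c(1, 2, 2, 3, 5)
  y <- c(1, 3, 2, 4, 4)
  expect_equal(spearman_cor(x, y)$rho, oracle_spearman_rho(x, y),
               tolerance = 1e-10)
  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:6, 12, replace = TRUE)
    b <- sample(1:6, 12, replace = TRUE)
    expect_equal(spearman_cor(a, b)$rho, oracle_spearman_rho(a, b),
                 tolerance = 1e-10)
    # cross-check rho and the t-approximation p against the reference
    # implementation's independent S-statistic route
    ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(spearman_cor(a, b)$rho, unname(ct$estimate), tolerance = 1e-9)
    expect_equal(spearman_cor(a, b)$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("correlation guards: length, minimum n, missing values", {
  expect_error(spearman_cor(1:4, 1:4), class = "infotrend_cor_error")
  expect_error(spearman_cor(1:6, 1:5), class = "infotrend_cor_error")
  expect_error(spearman_cor(c(1:5, NA), 1:6), class = "infotrend_cor_error")
})

test_that("panel screen: tiers, ordering, and the self-correlation case", {
  sim <- simulate_rsv(synth_config(seed = 19))
  panel <- tibble::tibble(date = sim$series$date, self = sim$series$value)
  rec <- correlate_panel(panel, sim$series)
  expect_identical(rec$rho, 1)
  expect_identical(rec$tier, "p<.001")
  expect_identical(rec$n_effective, 68L)
  expect_identical(attr(rec, "n_tests"), 1L)

  st <- simulate_study(synth_config(seed = 19, missing_rate = 0))
  screen <- correlate_panel(st$panel, st$rsv)
  expect_identical(screen$parameter, setdiff(names(st$panel), "date"))
  expect_true(all(screen$tier %in% c("none", "p<.05", "p<.001")))
  expect_true(all((screen$tier == "none") == (screen$p_value >= 0.05)))
  expect_true(all((screen$tier == "p<.001") == (screen$p_value < 0.001)))

  expect_error(correlate_panel(tibble::tibble(date = sim$series$date), sim$series),
               class = "infotrend_panel_error")
})

test_that("negative linkage in the generator is recovered as negative rho", {
  cfg <- synth_config(n_env_linked = 1, n_env_null = 0, link_sign = -1,
                      link_strength = 0.9, missing_rate = 0, seed = 23)
  st <- simulate_study(cfg)
  screen <- correlate_panel(st$panel, st$rsv)
  expect_lt(screen$rho, 0)
  expect_identical(screen$tier, "p<.001")
})

test_that("panel preprocessing excludes by rule and interpolates the rest", {
  dates <- month_grid("2018-12", 30)
  panel <- tibble::tibble(
    date = dates,
    ok = c(1, NA, 3:30),
    edge = c(NA, 2:30),
    holes = {
      v <- rnorm(30)
      v[sample(2:29, 12)] <- NA  # 40% missing
      v
    }
  )
  prep <- preprocess_panel(panel)
  expect_identical(names(prep$panel), c("date", "ok"))
  expect_equal(prep$panel$ok[2], 2)
  expect_identical(
    prep$exclusions,
    tibble::tibble(parameter = c("edge", "holes"),
                   reason = c("edge-missing", "excessive-missingness"))
  )
})

test_that("standardizing either input leaves Spearman rho unchanged", {
  sim <- simulate_rsv(synth_config(seed = 29))
  st <- simulate_study(synth_config(seed = 29, missing_rate = 0))
  raw <- correlate_panel(st$panel, st$rsv)
  z_panel <- st$panel
  for (p in setdiff(names(z_panel), "date")) {
    z_panel[[p]] <- (z_panel[[p]] - mean(z_panel[[p]])) / sd(z_panel[[p]])
  }
  z <- correlate_panel(z_panel, standardize(st$rsv))
  expect_equal(z$rho, raw$rho, tolerance = 1e-12)
})
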