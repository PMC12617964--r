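test_that("noiseless flat configuration yields a constant series with zero true MID", {
  cfg <- synth_config(n_months = 24, trend_kind = "none", base_level = 50,
                      seasonal_amplitude = 0, noise_sd = 0)
  sim <- simulate_rsv(cfg)
  expect_equal(sim$series$value, rep(50, 24))
  expect_identical(sim$truth$true_mid, 0)
})

test_that("linear trend is constructed with exactly the recorded slope", {
  n <- 36
  rise <- 21
  cfg <- synth_config(n_months = n, trend_kind = "linear",
                      trend_total_rise = rise, noise_sd = 0,
                      seasonal_amplitude = 0)
  sim <- simulate_rsv(cfg)
  expect_equal(diff(sim$series$value), rep(rise / (n - 1), n - 1))
  expect_identical(sim$truth$true_mid, rise / (n - 1))
})

test_that("identical config and seed reproduce bit-identical outputs", {
  cfg <- synth_config(seed = 77)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$rsv, b$rsv)
  expect_identical(a$control, b$control)
  expect_identical(a$panel, b$panel)
})

test_that("per-series RNG streams: appending a series leaves earlier ones untouched", {
  base <- synth_config(n_env_linked = 2, n_env_null = 1, seed = 3)
  more <- synth_config(n_env_linked = 2, n_env_null = 3, seed = 3)
  rsv <- simulate_rsv(base)
  p1 <- simulate_env_panel(base, rsv)$panel
  p2 <- simulate_env_panel(more, rsv)$panel
  expect_identical(p1[c("linked_1", "linked_2", "null_1")],
                   p2[c("linked_1", "linked_2", "null_1")])
})

test_that("perfect noiseless monotone linkage gives Spearman rho of exactly link_sign", {
  cfg <- synth_config(n_months = 30, trend_kind = "smooth_rise",
                      trend_total_rise = 40, noise_sd = 0,
                      seasonal_amplitude = 0, n_env_linked = 2, n_env_null = 0,
                      link_strength = 1, link_lag = 0, link_sign = c(1, -1),
                      missing_rate = 0)
  sim <- simulate_rsv(cfg)
  env <- simulate_env_panel(cfg, sim)
  expect_identical(cor(env$panel$linked_1, sim$series$value, method = "spearman"), 1)
  expect_identical(cor(env$panel$linked_2, sim$series$value, method = "spearman"), -1)
})

test_that("missingness is interior-only and absent when the rate is zero", {
  cfg0 <- synth_config(missing_rate = 0, seed = 5)
  sim <- simulate_rsv(cfg0)
  expect_false(anyNA(simulate_env_panel(cfg0, sim)$panel |> dplyr::select(-date)))

  cfg <- synth_config(missing_rate = 0.3, n_env_linked = 2, n_env_null = 2,
                      seed = 5)
  env <- simulate_env_panel(cfg, simulate_rsv(cfg))
  vals <- env$panel |> dplyr::select(-date)
  expect_true(anyNA(vals))
  expect_false(anyNA(vals[1, ]))
  expect_false(anyNA(vals[nrow(vals), ]))
  expect_identical(
    sort(unique(env$truth$masked$parameter)),
    sort(names(vals)[colSums(is.na(vals)) > 0])
  )
})

test_that("RSV values are clipped into the 0-100 range after noise", {
  cfg <- synth_config(trend_kind = "smooth_rise", base_level = 70,
                      trend_total_rise = 40, noise_sd = 25, seed = 11)
  v <- simulate_rsv(cfg)$series$value
  expect_true(all(v >= 0 & v <= 100))
  expect_true(any(v == 100))  # clipping active under this extreme configuration
})

test_that("invalid configurations are rejected at construction or generation", {
  expect_error(synth_config(n_months = 23), class = "infotrend_config_error")
  expect_error(synth_config(missing_rate = 0.31), class = "infotrend_config_error")
  expect_error(synth_config(link_strength = 1.2), class = "infotrend_config_error")
  expect_error(synth_config(link_sign = 2), class = "infotrend_config_error")
  cfg <- synth_config(n_months = 24, link_lag = 12)
  expect_error(simulate_env_panel(cfg, simulate_rsv(cfg)),
               class = "infotrend_config_error")
})
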