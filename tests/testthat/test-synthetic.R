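test_that("temperature generator is deterministic and degenerates correctly", {
  cfg <- tiny_config()
  a <- simulate_temperature(cfg, 1)
  b <- simulate_temperature(cfg, 1)
  expect_identical(a, b)
  expect_false(identical(a$tmean, simulate_temperature(cfg, 2)$tmean))

  flat <- tiny_config(seasonal_temp_amplitude = 0, temp_noise_sd = 0)
  tm <- simulate_temperature(flat, 1)$tmean
  expect_equal(tm, rep(flat$seasonal_temp_mean, length(tm)))
  expect_equal(length(tm), length(seq(as.Date("2017-01-01"),
                                      as.Date("2019-12-31"), by = "day")))
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  cfg <- tiny_config(n_years = 12, seasonal_temp_amplitude = 0,
                     temp_ar1 = 0.7, temp_noise_sd = 2)
  x <- simulate_temperature(cfg, 1)$tmean - cfg$seasonal_temp_mean
  r1 <- stats::acf(x, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(r1 - 0.7), 0.1)
  expect_lt(abs(stats::sd(x) - 2), 0.3)
})

test_that("mortality counts match the configured mean model", {
  # null curve, no seasonality, Poisson: sample mean within 3 SE of baseline
  cfg <- tiny_config(n_years = 5,
                     true_curve_params = list(mmt = 19, heat_coef = 0,
                                              cold_coef = 0, scale = 10),
                     mort_seasonal_amplitude = 0, overdispersion = 1,
                     baseline_daily_deaths = 40)
  d <- simulate_mortality(cfg, 1)$deaths
  se <- sqrt(40 / length(d))
  expect_lt(abs(mean(d) - 40), 3 * se)
  expect_true(all(d >= 0), all(d == round(d)))

  # Poisson property: variance/mean ratio near 1 on many draws
  expect_lt(abs(stats::var(d) / mean(d) - 1), 0.15)

  # overdispersed counts show the configured inflation
  cfg2 <- tiny_config(n_years = 5,
                      true_curve_params = list(mmt = 19, heat_coef = 0,
                                               cold_coef = 0, scale = 10),
                      mort_seasonal_amplitude = 0, overdispersion = 2,
                      baseline_daily_deaths = 40)
  d2 <- simulate_mortality(cfg2, 1)$deaths
  expect_gt(stats::var(d2) / mean(d2), 1.5)
})

test_that("heterogeneity controls between-location curve spread", {
  cfg0 <- tiny_config(heterogeneity_sd = 0)
  expect_identical(location_true_curve(cfg0, 1), location_true_curve(cfg0, 5))
  cfg1 <- tiny_config(heterogeneity_sd = 0.2)
  expect_false(identical(location_true_curve(cfg1, 1),
                         location_true_curve(cfg1, 2)))
  # true log-RR at the true MMT is exactly zero
  p <- location_true_curve(cfg1, 3)
  expect_identical(true_logrr(p$mmt, p), 0)
})

test_that("climate model series carry bias, trend and distinct streams", {
  cfg <- tiny_config(model_bias_mean = 2, model_bias_sd = 0,
                     model_sensitivity_sd = 0, warming_rate = 0.3,
                     temp_noise_sd = 0)
  ms <- simulate_model_series(cfg, 1, 1)
  # noise-free: model minus the seasonal cycle equals bias + linear trend
  seasonal <- cfg$seasonal_temp_mean + cfg$seasonal_temp_amplitude *
    cos(2 * pi * (as.POSIXlt(ms$daily$date)$yday + 1 - 196) / 365.25)
  resid <- ms$daily$tmean - seasonal
  yr <- as.numeric(ms$daily$date - as.Date("2000-01-01")) / 365.25
  expect_equal(resid, 2 + 0.03 * yr, tolerance = 1e-10)

  cfgN <- tiny_config(n_models = 5)
  series <- lapply(1:5, function(m) simulate_model_series(cfgN, 1, m)$daily$tmean)
  expect_equal(length(unique(vapply(series, function(s) s[100], 0))), 5)
})

test_that("global anomaly crosses warming levels at the closed-form year", {
  # 0.3 C/decade from 0 anomaly reaches +1.5 C in year 50
  an <- data.frame(model_id = "m", year = 1:100, anomaly = 0.03 * (1:100))
  w <- gwl_windows(an, levels = 1.5)
  expect_equal(w$crossing_year, 50)
  expect_equal(c(w$start_year, w$end_year), c(41, 60))
})

test_that("covid table arithmetic is consistent", {
  cfg <- tiny_config(n_locations = 6)
  tab <- simulate_covid_table(cfg)
  expect_equal(nrow(tab), 6)
  total <- tab$crude_rate_per_1000 * tab$population / 1000
  expect_true(all(tab$deaths_2020 <= total & tab$deaths_2021 <= total))
  expect_true(all(tab$deaths_2020 >= 0 & tab$deaths_2021 >= 0))
  expect_identical(tab, simulate_covid_table(cfg))
})

test_that("study bundle is reproducible and csv round-trips", {
  cfg <- tiny_config(n_years = 2)
  study <- simulate_study(cfg)
  expect_identical(study$series[[1]], simulate_study(cfg)$series[[1]])
  dir <- withr::local_tempdir()
  write_study_csvs(study, dir)
  back <- read_study_csvs(dir)
  expect_equal(back$series[[1]]$deaths, study$series[[1]]$deaths)
  expect_equal(back$series[[1]]$tmean, study$series[[1]]$tmean,
               tolerance = 1e-9)
  rep <- validate_inputs(dir)
  expect_length(rep$errors, 0)
})

test_that("configuration invariants are enforced", {
  expect_error(tiny_config(temp_ar1 = 1), "temp_ar1")
  expect_error(tiny_config(overdispersion = 0.5), "overdispersion")
  expect_error(tiny_config(temp_noise_sd = -1), "non-negative")
  expect_error(tiny_config(baseline_daily_deaths = -3), "positive")
})
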