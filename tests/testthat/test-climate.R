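test_that("GWL windows match closed form and the exhaustive scan", {
  an <- data.frame(model_id = "lin", year = 1:120, anomaly = 0.03 * (1:120))
  w <- gwl_windows(an, levels = c(1, 1.5, 2, 3))
  # linear closed form: centred 20-year mean is 0.03 * (y + 0.5)
  expect_equal(w$crossing_year, c(ceiling(1 / 0.03 - 0.5), 50,
                                  ceiling(2 / 0.03 - 0.5),
                                  ceiling(3 / 0.03 - 0.5)))
  expect_true(all(w$end_year - w$start_year + 1 == 20))
  # ordering invariant: start years non-decreasing in level
  expect_true(all(diff(w$start_year) >= 0))

  # arbitrary wiggly series: exhaustive 20-year-mean scan agrees
  set.seed(5)
  an2 <- data.frame(model_id = "wig", year = 1951:2100,
                    anomaly = cumsum(rnorm(150, 0.02, 0.05)))
  for (lev in c(0.5, 1, 1.5)) {
    expected <- bf_gwl_crossing(an2$year, an2$anomaly, lev)
    if (is.na(expected)) {
      expect_warning(gwl_windows(an2, levels = lev), "never reaches")
    } else {
      expect_equal(gwl_windows(an2, levels = lev)$crossing_year, expected)
    }
  }

  # flat series below every level: no windows, one warning per level
  flat <- data.frame(model_id = "flat", year = 1:60, anomaly = 0.5)
  expect_warning(
    expect_warning(w0 <- gwl_windows(flat, levels = c(1, 2)),
                   "never reaches"),
    "never reaches"
  )
  expect_equal(nrow(w0), 0)
  expect_error(gwl_windows(flat[1:10, ], levels = 1), "shorter")
})

test_that("quantile mapping is exact for identity and constant shifts", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2005-12-31"), by = "day")
  set.seed(9)
  st <- data.frame(date = dates,
                   tmean = 15 + 8 * cos(2 * pi * (seq_along(dates) %% 365) /
                                          365) + rnorm(length(dates), 0, 3))
  qm_id <- quantile_map(st, st, by_month = FALSE)
  expect_equal(predict(qm_id, st), st$tmean, tolerance = 1e-10)

  shifted <- st; shifted$tmean <- st$tmean + 2
  qm_sh <- quantile_map(shifted, st, by_month = FALSE)
  m <- qm_sh$maps[[1]]
  expect_equal(m$mq - m$sq, rep(2, length(m$mq)), tolerance = 1e-10)
  expect_equal(predict(qm_sh, shifted), st$tmean, tolerance = 1e-10)

  # monthly maps handle the same shift
  qm_mo <- quantile_map(shifted, st, by_month = TRUE)
  expect_equal(predict(qm_mo, shifted), st$tmean, tolerance = 1e-9)
})

test_that("calibration closure: corrected model quantiles match the station", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2010-12-31"), by = "day")
  set.seed(13)
  n <- length(dates)
  season <- 8 * cos(2 * pi * (seq_len(n) %% 365.25) / 365.25)
  st <- data.frame(date = dates, tmean = 15 + season + rnorm(n, 0, 3))
  md <- data.frame(date = dates, tmean = 16.5 + 1.2 * season +
                     rnorm(n, 0, 4))
  qm <- quantile_map(md, st, by_month = FALSE)
  corrected <- predict(qm, md)
  probs <- qm$probs
  expect_lt(max(abs(stats::quantile(corrected, probs, type = 1) -
                      stats::quantile(st$tmean, probs, type = 1))), 1e-6)
})

test_that("bias correction is monotone and preserves rank order", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  set.seed(17)
  st <- data.frame(date = dates, tmean = rnorm(length(dates), 15, 5))
  md <- data.frame(date = dates, tmean = rnorm(length(dates), 18, 7))
  qm <- quantile_map(md, st, by_month = FALSE)
  v <- sort(runif(200, -5, 40))   # spans both tails of the map
  cv <- predict(qm, data.frame(date = dates[1], tmean = v))
  expect_true(all(diff(cv) >= 0))
  corrected <- predict(qm, md)
  expect_identical(order(corrected), order(md$tmean))
})

test_that("a known constant bias is removed in the projection period", {
  # modest noise keeps sampling error of 10/20-year means well below the
  # 0.1 C tolerance this check is about
  cfg <- tiny_config(n_years = 10, model_bias_mean = 2, model_bias_sd = 0,
                     warming_rate = 0, model_sensitivity_sd = 0,
                     temp_noise_sd = 1)
  st <- simulate_temperature(cfg, 1)
  md <- simulate_model_series(cfg, 1, 1)$daily
  qm <- quantile_map(md[, c("date", "tmean")], st)
  proj <- md[md$date >= as.Date("2040-01-01") &
               md$date <= as.Date("2059-12-31"), c("date", "tmean")]
  corrected <- predict(qm, proj)
  # no warming configured: corrected projection mean should equal the
  # station generator's mean
  expect_lt(abs(mean(corrected) - cfg$seasonal_temp_mean), 0.1)
  expect_lt(abs(mean(proj$tmean) - (cfg$seasonal_temp_mean + 2)), 0.15)
})

test_that("nearest grid cell matches a brute-force distance scan", {
  set.seed(21)
  for (r in 1:5) {
    pts <- data.frame(lon = runif(12, -10, 10), lat = runif(12, 40, 50))
    grid <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
      data.frame(lon = pts$lon[i], lat = pts$lat[i], value = i)
    }))
    lon0 <- runif(1, -10, 10); lat0 <- runif(1, 40, 50)
    d <- geosphere::distHaversine(as.matrix(pts[, c("lon", "lat")]),
                                  c(lon0, lat0))
    expect_equal(unique(extract_nearest_gridcell(grid, lon0, lat0)$value),
                 which.min(d))
  }
  # exact coincidence returns that point's rows
  grid <- data.frame(lon = c(0, 5), lat = c(45, 45), value = c(1, 2))
  expect_equal(extract_nearest_gridcell(grid, 5, 45)$value, 2)
  # equidistant pair: (lat, lon) lexicographic winner, deterministically
  tie <- data.frame(lon = c(-1, 1), lat = c(45, 45), value = c(1, 2))
  expect_equal(extract_nearest_gridcell(tie, 0, 45)$value, 1)
  expect_error(extract_nearest_gridcell(tie[0, ], 0, 45), "empty")
})
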