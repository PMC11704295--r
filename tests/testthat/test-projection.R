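test_that("curve evaluation is continuous and linear beyond the boundary", {
  crv <- curve_from_function(function(t) 0.003 * (t - 19)^2)
  b <- crv$boundary[2]
  # continuity at the boundary knot
  expect_equal(predict(crv, b), predict(crv, b + 1e-9), tolerance = 1e-6)
  # linearity beyond: equal increments in T give equal increments in log-RR
  lr <- predict(crv, b + c(1, 2, 3, 7))
  d <- diff(lr) / diff(c(1, 2, 3, 7))
  expect_equal(d, rep(d[1], 3), tolerance = 1e-10)
  # the extrapolation slope equals the inside finite-difference slope
  eps <- 1e-6
  slope_in <- (predict(crv, b) - predict(crv, b - eps)) / eps
  slope_out <- (predict(crv, b + 2) - predict(crv, b + 1)) / 1
  expect_lt(abs(slope_in - slope_out), 1e-4)
  expect_error(predict(crv, NaN), "non-finite")
})

test_that("attributable deaths follow the AF closed form", {
  crv <- curve_from_function(function(t) 0.004 * (t - 19)^2)
  # all days at or below the MMT: nothing attributable
  cold <- rep(crv$mmt - 5, 365)
  res <- attributable_heat(crv, cold, 100)
  expect_identical(res$an_per_year, 0)
  expect_identical(res$heat_fraction, 0)

  # one day per year with RR = 2 contributes AF = 0.5 -> 50 deaths/year
  t_rr2 <- uniroot(function(t) predict(crv, t) - log(2),
                   c(crv$mmt, 60))$root
  temps <- c(rep(crv$mmt - 5, 364), t_rr2)
  res2 <- attributable_heat(crv, temps, 100, n_years = 1)
  expect_equal(res2$an_per_year, 50, tolerance = 1e-6)

  # the heat fraction is invariant to the baseline level
  res3 <- attributable_heat(crv, temps, 10, n_years = 1)
  expect_equal(res2$heat_fraction, res3$heat_fraction, tolerance = 1e-12)
  expect_error(attributable_heat(crv, temps, 0), "positive")
})

test_that("pipeline heat fraction matches the numerically integrated truth", {
  cfg <- sim_config(n_locations = 1, n_years = 10, n_models = 1,
                    overdispersion = 1.2, heterogeneity_sd = 0, seed = 4)
  s <- simulate_mortality(cfg, 1)
  crv <- cumulative_curve(heat_dlnm(s))
  truth <- location_true_curve(cfg, 1)
  # a 2 C warmer future window drawn from the same generator family
  w <- simulate_temperature(cfg, 99)
  temps <- w$tmean + 2
  est <- attributable_heat(crv, temps, cfg$baseline_daily_deaths)$heat_fraction
  h_true <- true_heat_fraction(truth, temps)
  expect_lt(abs(est - h_true) / h_true, 0.10)
})

test_that("warming a window never decreases attributable deaths", {
  crv <- curve_from_function(function(t) 0.004 * (t - 19)^2)
  set.seed(31)
  temps <- rnorm(2000, 16, 6)
  an <- vapply(c(0, 0.5, 1, 2, 3), function(delta) {
    attributable_heat(crv, temps + delta, 50)$an_per_year
  }, 0)
  expect_true(all(diff(an) >= 0))
})

test_that("Monte-Carlo intervals degenerate and converge as expected", {
  crv <- curve_from_function(function(t) 0.004 * (t - 19)^2)
  temps <- rnorm(3000, 18, 5)
  # zero coefficient covariance, one model: the eCI collapses to a point
  imp <- project_heat(crv, list(m1 = temps), level = 1.5,
                      baseline_daily_deaths = 50, n_sim = 50, seed = 1)
  ens <- imp[imp$model_id == "ensemble", ]
  expect_equal(ens$ci_lower, ens$ci_median, tolerance = 1e-12)
  expect_equal(ens$ci_median, ens$ci_upper, tolerance = 1e-12)

  # seeded runs are bit-reproducible
  crv2 <- crv; crv2$vcov <- diag(1e-4, 4)
  a <- project_heat(crv2, list(m1 = temps), 1.5, 50, n_sim = 100, seed = 9)
  b <- project_heat(crv2, list(m1 = temps), 1.5, 50, n_sim = 100, seed = 9)
  expect_identical(attr(a, "draws"), attr(b, "draws"))

  # doubling the draws moves the median by less than 2% of h
  big <- project_heat(crv2, list(m1 = temps), 1.5, 50, n_sim = 200, seed = 9)
  m1 <- a[a$model_id == "ensemble", "ci_median"]
  m2 <- big[big$model_id == "ensemble", "ci_median"]
  expect_lt(abs(m1 - m2), 0.02 * m1)

  # no model reaching the level: warning plus empty result
  expect_warning(empty <- project_heat(crv2, list(), 3, 50, n_sim = 10,
                                       seed = 1), "no model window")
  expect_equal(nrow(empty), 0)
})

test_that("case summaries preserve percentile ordering", {
  crv <- curve_from_function(function(t) 0.004 * (t - 19)^2)
  crv$vcov <- diag(1e-3, 4)
  temps <- rnorm(3000, 18, 5)
  imp <- project_heat(crv, list(m1 = temps, m2 = temps + 0.5), 2, 50,
                      n_sim = 150, seed = 2)
  cases <- summarize_cases(imp)
  h <- setNames(cases$heat_fraction, cases$case)
  expect_lte(h[["best"]], h[["average"]])
  expect_lte(h[["average"]], h[["worst"]])
  # the triple equals direct percentiles of the pooled draws
  qs <- stats::quantile(attr(imp, "draws"), c(0.025, 0.5, 0.975),
                        names = FALSE)
  expect_equal(unname(h), qs, tolerance = 1e-12)
})
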