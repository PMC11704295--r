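test_that("covid fraction reproduces the worked example", {
  # crude rate 10/1000 on a population of 1e6 implies 10,000 total deaths;
  # 2,000 covid deaths give a fraction of 20%
  cf <- covid_fraction(2000, 1500, crude_rate_per_1000 = 10,
                      population = 1e6)
  expect_equal(cf$total_deaths, 10000)
  expect_equal(cf$fraction, 0.20)
  expect_equal(cf$year_used, 2020L)

  # the year with the higher burden is selected
  expect_equal(covid_fraction(100, 300, 10, 1e6)$year_used, 2021L)
  expect_equal(covid_fraction(0, 0, 10, 1e6)$fraction, 0)
  expect_error(covid_fraction(20000, 0, 10, 1e6), "exceed")
  expect_error(covid_fraction(10, 10, 10, 0), "population")
})

test_that("years-to-equal matches hand calculations", {
  expect_equal(years_to_equal(0.20, 0.01)$years, 20)
  expect_equal(years_to_equal(0.20, 0.02)$years, 10)
  expect_equal(years_to_equal(0.05, 0.05)$years, 1)
  expect_warning(y0 <- years_to_equal(0.2, 0), "infinite")
  expect_identical(y0$years, Inf)
  expect_error(years_to_equal(-0.1, 0.01), "proportion")
  expect_error(years_to_equal(0.1, -0.01), "non-negative")
})

test_that("years-to-equal is homogeneous and monotone", {
  base <- years_to_equal(0.2, 0.01)$years
  for (k in c(0.5, 2, 10)) {
    expect_equal(years_to_equal(0.2 * k / 10, 0.01 * k / 10)$years, base,
                 tolerance = 1e-12)
  }
  hs <- c(0.005, 0.01, 0.02, 0.08)
  ys <- vapply(hs, function(h) years_to_equal(0.2, h)$years, 0)
  expect_true(all(diff(ys) < 0))
  cs <- c(0.05, 0.1, 0.2, 0.4)
  yc <- vapply(cs, function(cc) years_to_equal(cc, 0.01)$years, 0)
  expect_true(all(diff(yc) > 0))
})

make_cases <- function(loc, level, h) {
  data.frame(location = loc, level = level,
             case = c("best", "average", "worst"),
             heat_fraction = sort(h))
}

test_that("comparison table joins, orders and counts correctly", {
  impacts <- rbind(make_cases(1, 1.0, c(0.004, 0.01, 0.03)),
                   make_cases(1, 3.0, c(0.01, 0.022, 0.05)),
                   make_cases(2, 1.0, c(0.001, 0.002, 0.004)))
  covid <- data.frame(country = c("C01", "C02"),
                      deaths_2020 = c(2000, 500), deaths_2021 = c(1000, 800),
                      crude_rate_per_1000 = c(10, 8),
                      population = c(1e6, 2e6))
  metadata <- data.frame(location_id = c(1, 2), country = c("C01", "C02"))
  tab <- build_comparison_table(impacts, covid, metadata,
                                threshold_years = 10)
  expect_equal(nrow(tab), 9)
  # case ordering on every location x level: worst <= average <= best years
  for (key in unique(paste(tab$location, tab$level))) {
    sub <- tab[paste(tab$location, tab$level) == key, ]
    y <- setNames(sub$years_to_equal, sub$case)
    expect_lte(y[["worst"]], y[["average"]])
    expect_lte(y[["average"]], y[["best"]])
  }
  # counts equal a brute-force filter of the table
  counts <- attr(tab, "counts")
  for (r in seq_len(nrow(counts))) {
    expect_equal(counts$n_locations_within_threshold[r],
                 sum(tab$years_to_equal[tab$level == counts$level[r] &
                                          tab$case == counts$case[r]] <= 10))
  }
  # location 1 at +1.0: c = 0.2, average h = 0.01 -> exactly 20 years
  expect_equal(tab$years_to_equal[tab$location == 1 & tab$level == 1 &
                                    tab$case == "average"], 20)

  # inclusive threshold: 9.9 years counts, 10.0 counts, 10.1 does not
  imp_b <- make_cases(1, 1.0, c(0.2 / 10.1, 0.2 / 10, 0.2 / 9.9))
  tb <- build_comparison_table(imp_b, covid, metadata, threshold_years = 10)
  cb <- attr(tb, "counts")
  expect_equal(cb$n_locations_within_threshold[cb$case == "worst"], 1)
  expect_equal(cb$n_locations_within_threshold[cb$case == "average"], 1)
  expect_equal(cb$n_locations_within_threshold[cb$case == "best"], 0)
})

test_that("sub-national overrides and join errors behave", {
  impacts <- make_cases(1, 1.0, c(0.01, 0.01, 0.01))
  covid <- data.frame(country = c("C01", "C01"),
                      location_id = c(NA, 1),
                      deaths_2020 = c(2000, 4000), deaths_2021 = c(0, 0),
                      crude_rate_per_1000 = c(10, 10),
                      population = c(1e6, 1e6))
  metadata <- data.frame(location_id = 1, country = "C01")
  tab <- build_comparison_table(impacts, covid, metadata)
  # the sub-national row (fraction 0.4) wins over the national one (0.2)
  expect_equal(unique(tab$covid_fraction), 0.4)

  expect_error(
    build_comparison_table(make_cases(7, 1, c(0.01, 0.01, 0.01)),
                           covid, metadata),
    "missing from metadata"
  )
})

test_that("all-zero heat fractions yield no cities under any threshold", {
  impacts <- make_cases(1, 1.0, c(0, 0, 0))
  covid <- data.frame(country = "C01", deaths_2020 = 1000, deaths_2021 = 0,
                      crude_rate_per_1000 = 10, population = 1e6)
  metadata <- data.frame(location_id = 1, country = "C01")
  tab <- suppressWarnings(
    build_comparison_table(impacts, covid, metadata, threshold_years = 1000)
  )
  expect_true(all(is.infinite(tab$years_to_equal)))
  expect_true(all(attr(tab, "counts")$n_locations_within_threshold == 0))
})
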