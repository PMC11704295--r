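#' Configuration for the synthetic study generator
#'
#' Builds and validates the configuration driving the synthetic-data module.
#' The generator emulates the inputs of a multi-city heat-mortality study with
#' analytically known ground truth: seasonal autocorrelated station
#' temperatures, overdispersed daily death counts driven by a known U-shaped
#' cumulative exposure-response curve distributed over 21 days of lag,
#' between-location heterogeneity in that curve, biased climate-model series
#' with a warming trend and a global-mean anomaly track, and a country-level
#' COVID-19 mortality table.
#'
#' @param n_locations number of locations (cities), one country each.
#' @param n_years length of the observational record per location, ending
#'   December 2019.
#' @param baseline_daily_deaths expected daily all-cause deaths at the curve
#'   reference, per location.
#' @param seasonal_temp_mean,seasonal_temp_amplitude annual mean and seasonal
#'   half-range of daily mean temperature (degrees C).
#' @param temp_noise_sd stationary standard deviation of the AR(1) noise
#'   around the seasonal cycle (degrees C).
#' @param temp_ar1 lag-1 autocorrelation of the temperature noise, in `[0,1)`.
#' @param true_curve_params list with elements `mmt` (temperature of minimum
#'   mortality, degrees C), `heat_coef` and `cold_coef` (log-RR reached
#'   `scale` degrees above/below the MMT) and `scale` (degrees C). The true
#'   cumulative log-RR is an asymmetric parabola
#'   `f(T) = heat_coef * ((T - mmt)/scale)^2` above the MMT (mirrored with
#'   `cold_coef` below), so `f(mmt) = 0` exactly.
#' @param lag_decay geometric decay of lag-specific effects; lag weights
#'   `w_l` are proportional to `lag_decay^l` for lags 0..21 and normalised to
#'   sum to one, so the true cumulative curve equals `f` exactly.
#' @param heterogeneity_sd between-location spread: log-normal multiplier (sd
#'   on the log scale) on `heat_coef`/`cold_coef` and a normal shift with sd
#'   `10 * heterogeneity_sd` degrees C on the location MMT.
#' @param overdispersion variance/mean ratio of daily counts (>= 1); counts
#'   are negative-binomial with matching mean (Poisson when equal to 1).
#' @param mort_seasonal_amplitude amplitude of the seasonal log-mortality
#'   cycle (winter peak), absorbed by the time spline at the fitting stage.
#' @param n_models number of synthetic climate models.
#' @param model_bias_mean,model_bias_sd distribution of the constant
#'   per-model temperature bias (degrees C).
#' @param warming_rate ensemble-mean warming rate, degrees C per decade.
#' @param model_sensitivity_sd log-normal sd of the per-model multiplier on
#'   `warming_rate` (mimics differing climate sensitivities).
#' @param anomaly_noise_sd interannual sd of the global-mean anomaly around
#'   its linear track (degrees C); 0 gives a deterministic track.
#' @param anomaly_2000 global-mean anomaly relative to 1850-1900 assigned to
#'   the year 2000 (degrees C).
#' @param seed master integer seed; all sub-streams derive from it.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_locations = 2, n_years = 3, n_models = 2)
#' str(cfg[c("n_locations", "n_years", "seed")])
#' @export
sim_config <- function(n_locations = 38,
                       n_years = 29,
                       baseline_daily_deaths = 50,
                       seasonal_temp_mean = 15,
                       seasonal_temp_amplitude = 8,
                       temp_noise_sd = 3,
                       temp_ar1 = 0.7,
                       true_curve_params = list(mmt = 19, heat_coef = 0.35,
                                                cold_coef = 0.10, scale = 10),
                       lag_decay = 0.6,
                       heterogeneity_sd = 0.15,
                       overdispersion = 1.3,
                       mort_seasonal_amplitude = 0.10,
                       n_models = 31,
                       model_bias_mean = 1.0,
                       model_bias_sd = 1.5,
                       warming_rate = 0.3,
                       model_sensitivity_sd = 0.1,
                       anomaly_noise_sd = 0,
                       anomaly_2000 = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_locations = n_locations, n_years = n_years,
    baseline_daily_deaths = baseline_daily_deaths,
    seasonal_temp_mean = seasonal_temp_mean,
    seasonal_temp_amplitude = seasonal_temp_amplitude,
    temp_noise_sd = temp_noise_sd, temp_ar1 = temp_ar1,
    true_curve_params = true_curve_params,
    lag_decay = lag_decay, heterogeneity_sd = heterogeneity_sd,
    overdispersion = overdispersion,
    mort_seasonal_amplitude = mort_seasonal_amplitude,
    n_models = n_models, model_bias_mean = model_bias_mean,
    model_bias_sd = model_bias_sd, warming_rate = warming_rate,
    model_sensitivity_sd = model_sensitivity_sd,
    anomaly_noise_sd = anomaly_noise_sd, anomaly_2000 = anomaly_2000,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_locations)) stop_config("n_locations must be a count >= 1")
  if (!is_count(cfg$n_years)) stop_config("n_years must be a count >= 1")
  if (!is_count(cfg$n_models)) stop_config("n_models must be a count >= 1")
  if (!is.numeric(cfg$baseline_daily_deaths) || cfg$baseline_daily_deaths <= 0)
    stop_config("baseline_daily_deaths must be positive")
  for (nm in c("seasonal_temp_amplitude", "temp_noise_sd", "heterogeneity_sd",
               "model_bias_sd", "model_sensitivity_sd", "anomaly_noise_sd",
               "mort_seasonal_amplitude")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
      stop_config("%s must be a non-negative scale", nm)
  }
  if (cfg$temp_ar1 < 0 || cfg$temp_ar1 >= 1)
    stop_config("temp_ar1 must lie in [0, 1)")
  if (cfg$overdispersion < 1)
    stop_config("overdispersion must be >= 1")
  if (cfg$lag_decay <= 0)
    stop_config("lag_decay must be positive")
  p <- cfg$true_curve_params
  if (!all(c("mmt", "heat_coef", "cold_coef", "scale") %in% names(p)))
    stop_config("true_curve_params must name mmt, heat_coef, cold_coef, scale")
  invisible(cfg)
}

# Observational calendar: n_years full calendar years ending 2019-12-31,
# matching the late-period records of multi-city mortality databases.
obs_dates <- function(config) {
  seq(as.Date(sprintf("%d-01-01", 2020 - config$n_years)),
      as.Date("2019-12-31"), by = "day")
}

model_dates <- function(config) {
  seq(as.Date("2000-01-01"), as.Date("2119-12-31"), by = "day")
}

MAX_LAG_DAYS <- 21L

# Shared station-like core: seasonal sinusoid (NH, peak mid-July) plus AR(1)
# noise with stationary sd temp_noise_sd.
temperature_core <- function(dates, mean, amplitude, ar1, sd, seed,
                             peak_doy = 196) {
  n <- length(dates)
  seasonal <- mean + amplitude * cos(2 * pi * (day_of_year(dates) - peak_doy) /
                                       365.25)
  if (sd == 0) return(seasonal)
  set.seed(seed)
  innov_sd <- sd * sqrt(1 - ar1^2)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    eta <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) e[t] <- ar1 * e[t - 1] + eta[t - 1]
  }
  seasonal + e
}

# Canonical station generation includes a 21-day burn-in so that mortality at
# the first observational day has a full lag history.
station_extended <- function(config, location_id) {
  d <- obs_dates(config)
  dext <- seq(d[1] - MAX_LAG_DAYS, d[length(d)], by = "day")
  tm <- temperature_core(
    dext, config$seasonal_temp_mean, config$seasonal_temp_amplitude,
    config$temp_ar1, config$temp_noise_sd,
    substream_seed(config$seed, "temperature", location_id)
  )
  list(dates = dext, tmean = tm, n_burn = MAX_LAG_DAYS)
}

#' Simulate a location's daily temperature series
#'
#' @param config a [sim_config()].
#' @param location_id integer location identifier.
#' @return data frame with columns `date` and `tmean` covering the
#'   observational period.
#' @export
simulate_temperature <- function(config, location_id) {
  ext <- station_extended(config, location_id)
  keep <- (ext$n_burn + 1):length(ext$dates)
  data.frame(date = ext$dates[keep], tmean = ext$tmean[keep])
}

#' True cumulative exposure-response curve of a location
#'
#' Applies the between-location heterogeneity stream to the configured curve:
#' log-normal multipliers on the heat and cold coefficients and a normal shift
#' on the MMT. With `heterogeneity_sd = 0` every location shares the
#' configured curve.
#'
#' @inheritParams simulate_temperature
#' @return list with elements `mmt`, `heat_coef`, `cold_coef`, `scale`.
#' @export
location_true_curve <- function(config, location_id) {
  p <- config$true_curve_params
  if (config$heterogeneity_sd == 0) return(p)
  set.seed(substream_seed(config$seed, "heterogeneity", location_id))
  e <- stats::rnorm(3)
  list(
    mmt = p$mmt + 10 * config$heterogeneity_sd * e[3],
    heat_coef = p$heat_coef * exp(config$heterogeneity_sd * e[1]),
    cold_coef = p$cold_coef * exp(config$heterogeneity_sd * e[2]),
    scale = p$scale
  )
}

#' Evaluate a true cumulative log-RR curve
#'
#' @param temps numeric temperatures (degrees C).
#' @param params curve parameter list as from [location_true_curve()].
#' @return numeric log relative risks; exactly 0 at `params$mmt`.
#' @export
true_logrr <- function(temps, params) {
  z <- (temps - params$mmt) / params$scale
  ifelse(z >= 0, params$heat_coef * z^2, params$cold_coef * z^2)
}

# Normalised geometric lag weights over lags 0..21.
lag_weights <- function(decay) {
  w <- decay^(0:MAX_LAG_DAYS)
  w / sum(w)
}

#' Simulate a location's daily death counts
#'
#' Counts are drawn from an overdispersed Poisson (negative binomial with
#' matching mean; plain Poisson when `overdispersion == 1`) with
#' `log mean = log(baseline) + seasonal cycle + sum_l w_l f(T[t-l])`, where
#' `f` is the location's true cumulative log-RR curve and `w_l` the
#' normalised geometric lag weights over lags 0..21.
#'
#' @inheritParams simulate_temperature
#' @param temps optional extended temperature list from the internal
#'   generator; by default the location's own canonical series is used.
#' @return data frame with columns `date`, `deaths`, `tmean`.
#' @export
simulate_mortality <- function(config, location_id, temps = NULL) {
  if (config$baseline_daily_deaths <= 0)
    stop_config("baseline_daily_deaths must be positive")
  ext <- temps %||% station_extended(config, location_id)
  params <- location_true_curve(config, location_id)
  w <- lag_weights(config$lag_decay)
  f <- true_logrr(ext$tmean, params)
  eff <- as.numeric(stats::filter(f, w, method = "convolution", sides = 1))
  keep <- (ext$n_burn + 1):length(ext$dates)
  dates <- ext$dates[keep]
  seasonal <- config$mort_seasonal_amplitude *
    cos(2 * pi * (day_of_year(dates) - 15) / 365.25)
  mu <- exp(log(config$baseline_daily_deaths) + seasonal + eff[keep])
  set.seed(substream_seed(config$seed, "mortality", location_id))
  phi <- config$overdispersion
  deaths <- if (phi == 1) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = mu / (phi - 1))
  }
  data.frame(date = dates, deaths = deaths, tmean = ext$tmean[keep])
}

# Per-model attributes are drawn on a model-only stream so they are identical
# across locations and unaffected by adding locations.
model_attributes <- function(config, model_id) {
  set.seed(substream_seed(config$seed, "model", 0L, model_id))
  bias <- stats::rnorm(1, config$model_bias_mean, config$model_bias_sd)
  sens <- exp(stats::rnorm(1, 0, config$model_sensitivity_sd))
  list(bias = bias, rate = config$warming_rate * sens)
}

#' Simulate one climate model's series for a location
#'
#' The daily series is a station-like generator (same seasonal structure as
#' the location, independent noise) plus a constant per-model bias and a
#' linear warming trend at the model's own rate; the annual global-mean
#' anomaly series (relative to 1850-1900) rises at the same rate.
#'
#' @inheritParams simulate_temperature
#' @param model_id integer model identifier.
#' @return list with `daily` (data frame: `model_id`, `date`, `tmean`,
#'   2000-2119) and `anomaly` (data frame: `model_id`, `year`, `anomaly`,
#'   1990-2130).
#' @export
simulate_model_series <- function(config, location_id, model_id) {
  att <- model_attributes(config, model_id)
  dates <- model_dates(config)
  base <- temperature_core(
    dates, config$seasonal_temp_mean, config$seasonal_temp_amplitude,
    config$temp_ar1, config$temp_noise_sd,
    substream_seed(config$seed, "model", location_id, model_id)
  )
  yr_frac <- as.numeric(dates - as.Date("2000-01-01")) / 365.25
  daily <- data.frame(
    model_id = model_id, date = dates,
    tmean = base + att$bias + att$rate / 10 * yr_frac
  )
  list(daily = daily, anomaly = simulate_global_anomaly(config, model_id))
}

#' Simulate a model's annual global-mean temperature anomaly
#'
#' @inheritParams simulate_model_series
#' @return data frame with columns `model_id`, `year` (1990-2130) and
#'   `anomaly` (degrees C relative to 1850-1900).
#' @export
simulate_global_anomaly <- function(config, model_id) {
  att <- model_attributes(config, model_id)
  years <- 1990:2130
  anom <- config$anomaly_2000 + att$rate / 10 * (years - 2000)
  if (config$anomaly_noise_sd > 0) {
    set.seed(substream_seed(config$seed, "anomaly", 0L, model_id))
    anom <- anom + stats::rnorm(length(years), 0, config$anomaly_noise_sd)
  }
  data.frame(model_id = model_id, year = years, anomaly = anom)
}

#' Simulate the country-level COVID-19 mortality table
#'
#' One country per location. Total deaths implied by the crude death rate and
#' population always bound the COVID-19 deaths of either year.
#'
#' @inheritParams simulate_temperature
#' @return data frame with columns `country`, `deaths_2020`, `deaths_2021`,
#'   `crude_rate_per_1000`, `population`.
#' @export
simulate_covid_table <- function(config) {
  n <- config$n_locations
  set.seed(substream_seed(config$seed, "covid"))
  population <- round(stats::rlnorm(n, log(5e6), 0.6))
  crude_rate <- stats::runif(n, 6, 11)
  total <- crude_rate * population / 1000
  data.frame(
    country = sprintf("C%02d", seq_len(n)),
    deaths_2020 = round(total * stats::runif(n, 0.02, 0.25)),
    deaths_2021 = round(total * stats::runif(n, 0.02, 0.25)),
    crude_rate_per_1000 = crude_rate,
    population = population
  )
}

#' Simulate location metadata
#'
#' @inheritParams simulate_temperature
#' @return data frame with columns `location_id`, `country`, `region`,
#'   `climate_class`, `gdp_pc`, `lon`, `lat`.
#' @export
simulate_metadata <- function(config) {
  n <- config$n_locations
  set.seed(substream_seed(config$seed, "metadata"))
  regions <- c("Europe", "Asia", "North America", "South America",
               "Africa", "Oceania")
  classes <- c("Cfb", "Csa", "Dfb", "Aw", "BSk")
  data.frame(
    location_id = seq_len(n),
    country = sprintf("C%02d", seq_len(n)),
    region = rep_len(regions, n),
    climate_class = rep_len(classes, n),
    gdp_pc = exp(stats::rnorm(n, 10, 0.5)),
    lon = stats::runif(n, -180, 180),
    lat = stats::runif(n, -55, 70)
  )
}

#' Simulate a complete synthetic study
#'
#' Bundles every pipeline input: per-location daily mortality/temperature
#' series with their true curves, per-location-and-model climate series, the
#' global-mean anomaly table, location metadata and the COVID-19 table.
#'
#' @param config a [sim_config()].
#' @return list of class `heat_study` with elements `config`, `metadata`,
#'   `series` (list of data frames), `truth` (list of curve parameter lists),
#'   `model_daily` (list over locations of lists over models), `anomaly`
#'   (one data frame for all models) and `covid`.
#' @export
simulate_study <- function(config) {
  nl <- config$n_locations
  series <- vector("list", nl)
  truth <- vector("list", nl)
  model_daily <- vector("list", nl)
  for (i in seq_len(nl)) {
    series[[i]] <- simulate_mortality(config, i)
    truth[[i]] <- location_true_curve(config, i)
    model_daily[[i]] <- lapply(seq_len(config$n_models), function(m) {
      simulate_model_series(config, i, m)$daily
    })
  }
  anomaly <- do.call(rbind, lapply(seq_len(config$n_models), function(m) {
    simulate_global_anomaly(config, m)
  }))
  out <- list(config = config, metadata = simulate_metadata(config),
              series = series, truth = truth, model_daily = model_daily,
              anomaly = anomaly, covid = simulate_covid_table(config))
  class(out) <- "heat_study"
  out
}

#' @export
print.heat_study <- function(x, ...) {
  cat("Synthetic heat-mortality study\n")
  cat(sprintf("  locations: %d, years: %d, models: %d, seed: %d\n",
              x$config$n_locations, x$config$n_years, x$config$n_models,
              x$config$seed))
  invisible(x)
}

#' True annual heat-mortality fraction under a temperature series
#'
#' Numerically integrates the true curve over an (empirical) daily
#' temperature distribution: the mean over days of the attributable fraction
#' `(RR - 1)/RR` on days warmer than the true MMT. This is the ground truth
#' the estimation pipeline is benchmarked against.
#'
#' @param params true curve parameters ([location_true_curve()]).
#' @param temps daily temperatures representing the period of interest.
#' @return annual heat-mortality fraction (proportion of all deaths).
#' @export
true_heat_fraction <- function(params, temps) {
  rr <- exp(true_logrr(temps, params))
  af <- ifelse(temps > params$mmt, (rr - 1) / rr, 0)
  mean(af)
}

#' Write the study's CSV inputs
#'
#' Writes the same schemas the pipeline reads: per-location daily series
#' (`location_<id>.csv`: date, deaths, tmean), per-location model series
#' (`models_location_<id>.csv`: model_id, date, tmean), the global-mean
#' anomaly table (`global_anomaly.csv`), the COVID-19 table (`covid.csv`) and
#' metadata (`metadata.csv`).
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_study_csvs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(format_csv_numbers(df), path, row.names = FALSE,
                     quote = FALSE)
    files <<- c(files, path)
  }
  for (i in seq_along(study$series)) {
    wr(study$series[[i]], sprintf("location_%02d.csv", i))
    wr(do.call(rbind, study$model_daily[[i]]),
       sprintf("models_location_%02d.csv", i))
  }
  wr(study$anomaly, "global_anomaly.csv")
  wr(study$covid, "covid.csv")
  wr(study$metadata, "metadata.csv")
  invisible(files)
}

# 10 significant digits keeps reruns byte-identical within the float
# contract while remaining human-readable.
format_csv_numbers <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
    }
  }
  df
}
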