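#' COVID-19 mortality fraction of a country
#'
#' Total deaths are implied by the crude death rate (per 1000 people) and the
#' population; the COVID-19 fraction uses whichever of 2020 or 2021 carried
#' the higher burden.
#'
#' @param covid_2020,covid_2021 COVID-19 death counts for the two years.
#' @param crude_rate_per_1000 crude death rate per 1000 people.
#' @param population total population.
#' @param country optional label.
#' @return list of class `covid_fraction`: `country`, `year_used`,
#'   `covid_deaths`, `total_deaths`, `fraction`.
#' @examples
#' covid_fraction(2000, 1500, crude_rate_per_1000 = 10, population = 1e6)
#' @export
covid_fraction <- function(covid_2020, covid_2021, crude_rate_per_1000,
                           population, country = NA_character_) {
  if (population <= 0) stop_config("population must be positive")
  if (crude_rate_per_1000 <= 0) stop_config("crude rate must be positive")
  if (covid_2020 < 0 || covid_2021 < 0) stop_config("negative death counts")
  total <- crude_rate_per_1000 * population / 1000
  covid <- max(covid_2020, covid_2021)
  if (covid > total) {
    stop_config("inconsistent inputs: COVID-19 deaths (%.0f) exceed implied total deaths (%.0f)",
                covid, total)
  }
  year_used <- if (covid_2021 > covid_2020) 2021L else 2020L
  structure(list(country = country, year_used = year_used,
                 covid_deaths = covid, total_deaths = total,
                 fraction = covid / total),
            class = "covid_fraction")
}

#' @export
print.covid_fraction <- function(x, ...) {
  cat(sprintf("COVID-19 mortality fraction%s: %.2f%% (year %d, %.0f of %.0f deaths)\n",
              if (is.na(x$country)) "" else paste0(" [", x$country, "]"),
              100 * x$fraction, x$year_used, x$covid_deaths, x$total_deaths))
  invisible(x)
}

#' Years for cumulative heat deaths to equal one year of COVID-19 deaths
#'
#' The headline metric: the ratio of the COVID-19 mortality fraction (one
#' year) to the annual heat-mortality fraction. A COVID-19 fraction of 20
#' percent against a heat fraction of 1 percent per year gives 20 years. A
#' zero heat fraction returns `Inf` with a warning.
#'
#' @param covid a [covid_fraction()] or a bare proportion.
#' @param heat_fraction annual heat-mortality fraction (proportion).
#' @return list of class `years_to_equal`: `years`, `covid_fraction`,
#'   `heat_fraction`.
#' @examples
#' years_to_equal(0.20, 0.01)$years  # 20
#' @export
years_to_equal <- function(covid, heat_fraction) {
  c_frac <- if (inherits(covid, "covid_fraction")) covid$fraction else covid
  if (!is.numeric(c_frac) || c_frac < 0 || c_frac > 1) {
    stop_config("covid fraction must be a proportion in [0, 1]")
  }
  if (heat_fraction < 0) stop_config("heat fraction must be non-negative")
  years <- if (heat_fraction == 0) {
    warning("zero heat fraction: years-to-equal is infinite", call. = FALSE)
    Inf
  } else {
    c_frac / heat_fraction
  }
  structure(list(years = years, covid_fraction = c_frac,
                 heat_fraction = heat_fraction),
            class = "years_to_equal")
}

#' @export
print.years_to_equal <- function(x, ...) {
  cat(sprintf("%.3g years of heat deaths equal 1 year of COVID-19 deaths (c = %.2f%%, h = %.3f%%/yr)\n",
              x$years, 100 * x$covid_fraction, 100 * x$heat_fraction))
  invisible(x)
}

#' Comparison table of heat versus COVID-19 mortality
#'
#' Joins projected heat fractions (per location and warming level, three
#' cases each) to country-level COVID-19 fractions and computes the
#' years-to-equal metric, plus a summary counting locations whose average /
#' best / worst case reaches the COVID-19 benchmark within a threshold
#' number of years (inclusive).
#'
#' @param impacts data frame binding [summarize_cases()] rows (columns
#'   `location`, `level`, `case`, `heat_fraction`).
#' @param covid data frame in the covid CSV schema (`country`,
#'   `deaths_2020`, `deaths_2021`, `crude_rate_per_1000`, `population`),
#'   optionally with a `location_id` column for sub-national overrides that
#'   take precedence for matching locations.
#' @param metadata data frame with `location_id` and `country`.
#' @param threshold_years count threshold for the city-count summary.
#' @return object of class `heat_covid_comparison`: the per-row table
#'   (`location`, `level`, `case`, `heat_fraction`, `covid_fraction`,
#'   `years_to_equal`, `year_used`) with a `counts` attribute
#'   (`level` x `case` counts of locations within the threshold).
#' @export
build_comparison_table <- function(impacts, covid, metadata,
                                   threshold_years = 10) {
  stopifnot(all(c("location", "level", "case", "heat_fraction") %in%
                  names(impacts)))
  unmatched <- setdiff(unique(impacts$location), metadata$location_id)
  if (length(unmatched)) {
    stop_config("locations missing from metadata: %s",
                paste(unmatched, collapse = ", "))
  }
  cf_for <- function(loc) {
    if ("location_id" %in% names(covid)) {
      sub <- covid[!is.na(covid$location_id) & covid$location_id == loc, ]
      if (nrow(sub)) return(sub[1, ])
    }
    ctry <- metadata$country[match(loc, metadata$location_id)]
    row <- covid[covid$country == ctry, ]
    if ("location_id" %in% names(row)) row <- row[is.na(row$location_id), ]
    if (!nrow(row)) {
      stop_config("no COVID-19 record for location %s (country %s)",
                  loc, ctry)
    }
    row[1, ]
  }
  rows <- lapply(seq_len(nrow(impacts)), function(r) {
    rec <- cf_for(impacts$location[r])
    cf <- covid_fraction(rec$deaths_2020, rec$deaths_2021,
                         rec$crude_rate_per_1000, rec$population,
                         country = rec$country)
    y <- suppressWarnings(years_to_equal(cf, impacts$heat_fraction[r]))
    data.frame(location = impacts$location[r], level = impacts$level[r],
               case = impacts$case[r],
               heat_fraction = impacts$heat_fraction[r],
               covid_fraction = cf$fraction, years_to_equal = y$years,
               year_used = cf$year_used)
  })
  tab <- do.call(rbind, rows)
  counts <- stats::aggregate(
    years_to_equal ~ level + case, data = tab,
    FUN = function(v) sum(v <= threshold_years)
  )
  names(counts)[3] <- "n_locations_within_threshold"
  counts$threshold_years <- threshold_years
  structure(tab, class = c("heat_covid_comparison", "data.frame"),
            counts = counts)
}

#' @export
print.heat_covid_comparison <- function(x, digits = 3, ...) {
  cat("Heat vs COVID-19 mortality comparison\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("\nLocations reaching the COVID-19 benchmark within",
      attr(x, "counts")$threshold_years[1], "years:\n")
  print.data.frame(attr(x, "counts"), row.names = FALSE)
  invisible(x)
}
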