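#' Heat-attributable deaths and annual heat-mortality fraction
#'
#' For every day in the window with temperature above the curve's MMT, the
#' attributable fraction is `AF = (RR - 1)/RR` with `RR` the cumulative
#' relative risk at that day's temperature (log-linearly extrapolated beyond
#' the observed range). Attributable deaths are annualised over the window
#' and the heat fraction expresses them as a share of all deaths, so it is
#' invariant to the baseline level. AF is floored at zero, so days at or
#' below the MMT contribute exactly nothing.
#'
#' @param curve a `cumcurve` (typically a BLUP curve) with its MMT set.
#' @param temps daily temperatures over the window (degrees C).
#' @param baseline_daily_deaths expected deaths per day (held constant over
#'   projection windows: no adaptation or population change is modelled).
#' @param n_years window length in years (default `length(temps)/365.25`).
#' @return list with `an_per_year` (attributable deaths per year) and
#'   `heat_fraction` (annual proportion of all deaths attributable to heat).
#' @export
attributable_heat <- function(curve, temps, baseline_daily_deaths,
                              n_years = length(temps) / 365.25) {
  if (baseline_daily_deaths <= 0) stop_config("baseline must be positive")
  if (!length(temps)) stop_config("empty temperature window")
  if (is.na(curve$mmt)) stop_config("curve has no MMT")
  rr <- exp(predict(curve, temps))
  af <- pmax(0, (rr - 1) / rr)
  af[temps <= curve$mmt] <- 0
  an <- sum(af) * baseline_daily_deaths / n_years
  list(an_per_year = an,
       heat_fraction = an / (baseline_daily_deaths * 365.25))
}

#' Monte-Carlo projection of the heat-mortality fraction at one GWL
#'
#' Draws `n_sim` coefficient vectors from the curve's multivariate normal
#' sampling distribution, re-finds the MMT for each draw, and recomputes the
#' annual heat fraction for every draw under every model's bias-corrected
#' window. All draw-by-model values are pooled into one empirical
#' distribution whose 2.5th, 50th and 97.5th percentiles form the empirical
#' confidence interval, quantifying coefficient and across-model climate
#' uncertainty jointly.
#'
#' @param curve a `cumcurve` with positive semi-definite covariance.
#' @param window_temps named list (by model id) of corrected daily
#'   temperature vectors for this level's 20-year windows.
#' @param level the warming level (degrees C), carried into the output.
#' @param baseline_daily_deaths expected deaths per day.
#' @param n_sim number of Monte-Carlo draws (default 1000).
#' @param seed integer seed; results are bit-reproducible given it.
#' @param location label carried into the output.
#' @return object of class `heat_impact`: data frame of per-model point
#'   estimates (rows `model_id`) plus an `"ensemble"` row with the pooled
#'   `ci_lower`, `ci_median`, `ci_upper`; attributes keep the pooled draws.
#' @export
project_heat <- function(curve, window_temps, level, baseline_daily_deaths,
                         n_sim = 1000, seed = 1L, location = NA) {
  if (!length(window_temps)) {
    warning(sprintf("no model window at +%.1f C; empty result", level),
            call. = FALSE)
    return(empty_impact(location, level, n_sim, seed))
  }
  if (!is_count(n_sim)) stop_config("n_sim must be a count >= 1")
  set.seed(seed)
  draws <- MASS::mvrnorm(n_sim, curve$beta, curve$vcov)
  if (n_sim == 1) draws <- matrix(draws, nrow = 1)
  grid <- mmt_grid(curve)
  G <- curve_basis(curve, grid)
  gv <- G %*% t(draws)                       # ngrid x n_sim
  med <- curve$temp_percentiles[2]
  mmt_idx <- apply(gv, 2, function(col) {
    cand <- which(col <= min(col) + 1e-12)
    cand[which.min(abs(grid[cand] - med))]
  })
  mmt_draw <- grid[mmt_idx]
  center_draw <- gv[cbind(mmt_idx, seq_len(n_sim))]

  rows <- list(); pooled <- c()
  for (m in names(window_temps)) {
    temps <- window_temps[[m]]
    ny <- length(temps) / 365.25
    B <- curve_basis(curve, temps)
    LR <- B %*% t(draws)                     # ndays x n_sim
    LR <- sweep(LR, 2, center_draw)
    RR <- exp(LR)
    AF <- (RR - 1) / RR
    AF[AF < 0] <- 0
    AF[outer(temps, mmt_draw, "<=")] <- 0
    h_draws <- colSums(AF) / (ny * 365.25)
    pooled <- c(pooled, h_draws)
    pt <- attributable_heat(curve, temps, baseline_daily_deaths, ny)
    rows[[m]] <- data.frame(location = location, level = level,
                            model_id = m, an_per_year = pt$an_per_year,
                            heat_fraction = pt$heat_fraction,
                            ci_lower = NA_real_, ci_median = NA_real_,
                            ci_upper = NA_real_, n_sim = n_sim, seed = seed)
  }
  qs <- stats::quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE)
  ens <- data.frame(location = location, level = level,
                    model_id = "ensemble",
                    an_per_year = qs[2] * baseline_daily_deaths * 365.25,
                    heat_fraction = qs[2],
                    ci_lower = qs[1], ci_median = qs[2], ci_upper = qs[3],
                    n_sim = n_sim, seed = seed)
  out <- rbind(do.call(rbind, rows), ens)
  rownames(out) <- NULL
  structure(out, class = c("heat_impact", "data.frame"), draws = pooled)
}

empty_impact <- function(location, level, n_sim, seed) {
  template <- data.frame(location = location, level = level,
                         model_id = "none", an_per_year = 0,
                         heat_fraction = 0, ci_lower = 0, ci_median = 0,
                         ci_upper = 0, n_sim = n_sim, seed = seed)
  structure(template[0, ], class = c("heat_impact", "data.frame"),
            draws = numeric(0))
}

#' @export
print.heat_impact <- function(x, ...) {
  ens <- x[x$model_id == "ensemble", ]
  cat(sprintf("Heat-mortality projection at +%.1f C (%d models, %d draws)\n",
              ens$level[1] %||% NA, sum(x$model_id != "ensemble"),
              ens$n_sim[1] %||% NA))
  if (nrow(ens)) {
    cat(sprintf("  annual heat fraction: %.3f%% (95%% eCI %.3f%% - %.3f%%)\n",
                100 * ens$ci_median, 100 * ens$ci_lower, 100 * ens$ci_upper))
  }
  invisible(x)
}

#' Best/average/worst case summary of a projection
#'
#' The Monte-Carlo ensemble is summarised as three cases: the best case is
#' the lower bound of the empirical interval (fewest heat deaths, hence the
#' most years to reach the COVID-19 benchmark), the average case the median,
#' and the worst case the upper bound.
#'
#' @param impact a [project_heat()] result.
#' @return data frame with columns `location`, `level`, `case`
#'   (`best`/`average`/`worst`) and `heat_fraction`, plus a `mapping`
#'   attribute documenting the case-to-percentile correspondence.
#' @export
summarize_cases <- function(impact) {
  ens <- impact[impact$model_id == "ensemble", ]
  if (!nrow(ens)) stop_config("impact has no ensemble summary")
  out <- data.frame(
    location = ens$location[1], level = ens$level[1],
    case = c("best", "average", "worst"),
    heat_fraction = c(ens$ci_lower, ens$ci_median, ens$ci_upper)
  )
  attr(out, "mapping") <- c(best = "2.5th percentile (lower bound)",
                            average = "50th percentile (median)",
                            worst = "97.5th percentile (upper bound)")
  out
}
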