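#' Fit the first-stage quasi-Poisson DLNM for one location
#'
#' Regresses daily death counts on the temperature cross-basis, a natural
#' cubic spline of time with `df_per_year` degrees of freedom per year
#' (controls seasonality and long-term trends) and day-of-week indicators,
#' under a quasi-Poisson family (log link). The overdispersion parameter is
#' estimated from the Pearson statistic and inflates all standard errors by
#' its square root.
#'
#' @param series data frame with columns `date` (Date), `deaths`
#'   (non-negative integer) and `tmean` (degrees C), one row per day.
#' @param spec a [basis_spec()].
#' @param df_per_year degrees of freedom per year for the time spline
#'   (total df is `round(df_per_year * n_years)` with years counted as
#'   days/365.25, so leap days contribute their fraction).
#' @return object of class `heat_dlnm` with components `coefficients`,
#'   `vcov` (dispersion-scaled), `phi`, `cb_index` (columns of the
#'   cross-basis block), `converged`, basis metadata and the observed
#'   temperature summaries needed downstream. Methods: [print.heat_dlnm()],
#'   `coef`, `vcov`, `residuals`.
#' @examples
#' cfg <- sim_config(n_locations = 1, n_years = 2, n_models = 1,
#'                   overdispersion = 1)
#' fit <- heat_dlnm(simulate_mortality(cfg, 1))
#' fit
#' @export
heat_dlnm <- function(series, spec = basis_spec(), df_per_year = 8) {
  stopifnot(all(c("date", "deaths", "tmean") %in% names(series)))
  series <- series[order(series$date), , drop = FALSE]
  if (nrow(series) < 365) stop_config("need at least one full year of data")
  if (all(series$deaths == 0, na.rm = TRUE)) {
    stop_config("degenerate input: all death counts are zero")
  }
  if (any(series$deaths < 0, na.rm = TRUE)) {
    stop_config("negative death counts")
  }
  cb <- crossbasis(series$tmean, spec)
  n_years <- years_spanned(series$date)
  df_time <- max(3L, round(df_per_year * n_years))
  time_ns <- unclass(splines::ns(as.numeric(series$date), df = df_time))
  colnames(time_ns) <- sprintf("time.%d", seq_len(ncol(time_ns)))
  dow <- day_of_week(series$date)
  dow_mm <- stats::model.matrix(~dow)[, -1, drop = FALSE]
  X <- cbind(unclass(cb), time_ns, dow_mm)
  fit <- stats::glm(series$deaths ~ X, family = stats::quasipoisson(),
                    na.action = stats::na.exclude,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged) {
    stop(sprintf("first-stage IRLS did not converge (deviance %.4g after %d iterations)",
                 fit$deviance, fit$iter), call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  keep <- !is.na(coefs)
  if (!all(keep[seq_len(ncol(cb) + 1L)])) {
    stop_config("cross-basis block is rank deficient")
  }
  V <- sm$cov.scaled
  phi <- sm$dispersion
  cb_index <- 1L + seq_len(ncol(cb))   # after the intercept
  structure(list(
    coefficients = coefs[keep],
    vcov = V,
    phi = phi,
    cb_index = cb_index,
    spec = spec,
    var_knots = attr(cb, "var_knots"),
    boundary = attr(cb, "boundary"),
    lag_basis = attr(cb, "lag_basis"),
    vx = attr(cb, "vx"), vl = attr(cb, "vl"),
    temp_percentiles = stats::quantile(series$tmean, c(0.01, 0.5, 0.99),
                                       na.rm = TRUE, names = FALSE),
    deviance = fit$deviance,
    df_residual = fit$df.residual,
    df_time = df_time,
    n = sum(!is.na(fit$residuals)),
    converged = fit$converged,
    residuals_deviance = stats::residuals(fit, type = "deviance")
  ), class = "heat_dlnm")
}

#' @export
print.heat_dlnm <- function(x, ...) {
  cat("First-stage quasi-Poisson DLNM\n")
  cat(sprintf("  %d days used, %d coefficients (%d cross-basis), time spline df %d\n",
              x$n, length(x$coefficients), length(x$cb_index), x$df_time))
  cat(sprintf("  overdispersion (Pearson) phi = %.3f\n", x$phi))
  invisible(x)
}

#' @export
coef.heat_dlnm <- function(object, ...) object$coefficients

#' @export
vcov.heat_dlnm <- function(object, ...) object$vcov

#' @export
residuals.heat_dlnm <- function(object, ...) object$residuals_deviance

#' Wald test of the cross-basis block
#'
#' Tests the joint null that every cross-basis coefficient is zero (no
#' temperature-mortality association) with a chi-squared Wald statistic on
#' the dispersion-scaled covariance.
#'
#' @param fit a [heat_dlnm()] fit.
#' @return list with `statistic`, `df` and `p.value`.
#' @export
wald_crossbasis <- function(fit) {
  b <- fit$coefficients[fit$cb_index]
  V <- fit$vcov[fit$cb_index, fit$cb_index]
  stat <- drop(crossprod(b, solve(V, b)))
  df <- length(b)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Reduce a DLNM fit to its cumulative exposure-response curve
#'
#' Sums the fitted exposure-lag-response surface over the lag dimension:
#' `beta_red = (I_vx (x) s)' beta_cb` with `s` the column sums of the lag
#' basis over lags 0..`lag_max`, and the same linear map applied to the
#' covariance. The minimum mortality temperature (MMT) is located on a fine
#' grid and becomes the reference at which log-RR is exactly zero.
#'
#' @param fit a converged [heat_dlnm()] fit.
#' @param mmt_range percentile pair bounding the MMT search (defaults to the
#'   1st-99th observed percentiles, avoiding boundary artefacts).
#' @return object of class `cumcurve`: `beta` (length `v_x`), `vcov`,
#'   exposure knots and boundary, `mmt`, observed temperature summaries and
#'   the MMT search grid. Methods: `predict`, `plot`, `print`, `coef`,
#'   `vcov`, [find_mmt()].
#' @examples
#' cfg <- sim_config(n_locations = 1, n_years = 2, n_models = 1,
#'                   overdispersion = 1)
#' crv <- cumulative_curve(heat_dlnm(simulate_mortality(cfg, 1)))
#' crv
#' @export
cumulative_curve <- function(fit, mmt_range = c(1, 99)) {
  stopifnot(inherits(fit, "heat_dlnm"))
  if (!fit$converged) stop_config("first-stage fit did not converge")
  s <- colSums(fit$lag_basis)
  vx <- fit$vx; vl <- fit$vl
  M <- matrix(0, vx, vx * vl)
  for (j in seq_len(vx)) M[j, (j - 1L) * vl + seq_len(vl)] <- s
  beta_cb <- fit$coefficients[fit$cb_index]
  V_cb <- fit$vcov[fit$cb_index, fit$cb_index]
  curve <- new_cumcurve(
    beta = drop(M %*% beta_cb),
    vcov = M %*% V_cb %*% t(M),
    var_knots = fit$var_knots,
    boundary = fit$boundary,
    spec = fit$spec,
    temp_percentiles = fit$temp_percentiles,
    phi = fit$phi
  )
  curve$mmt <- find_mmt(curve, mmt_range)
  curve
}

new_cumcurve <- function(beta, vcov, var_knots, boundary, spec,
                         temp_percentiles, phi = NA_real_, mmt = NA_real_,
                         kind = "first-stage") {
  structure(list(beta = beta, vcov = (vcov + t(vcov)) / 2,
                 var_knots = var_knots, boundary = boundary, spec = spec,
                 temp_percentiles = temp_percentiles, phi = phi, mmt = mmt,
                 kind = kind),
            class = "cumcurve")
}

curve_basis <- function(curve, temps) {
  unclass(ns_eval(temps, knots = curve$var_knots,
                  boundary = curve$boundary))
}

mmt_grid <- function(curve, mmt_range = c(1, 99), step = 0.1) {
  lo <- curve$temp_percentiles[1]; hi <- curve$temp_percentiles[3]
  if (!identical(mmt_range, c(1, 99))) {
    # re-derive bounds by linear interpolation between stored percentiles
    # (1, 50, 99); exact bounds only matter at the defaults.
    pr <- c(1, 50, 99)
    lo <- stats::approx(pr, curve$temp_percentiles, mmt_range[1],
                        rule = 2)$y
    hi <- stats::approx(pr, curve$temp_percentiles, mmt_range[2],
                        rule = 2)$y
  }
  seq(lo, hi, by = step)
}

#' Locate the minimum mortality temperature of a cumulative curve
#'
#' Scans a fine temperature grid (0.1 degree C steps) between the requested
#' observed percentiles for the minimiser of the un-centred cumulative
#' log-RR. Ties are broken toward the median observed temperature.
#'
#' @param curve a `cumcurve`.
#' @param mmt_range percentile pair bounding the search.
#' @param step grid step in degrees C.
#' @return the MMT in degrees C.
#' @export
find_mmt <- function(curve, mmt_range = c(1, 99), step = 0.1) {
  grid <- mmt_grid(curve, mmt_range, step)
  val <- drop(curve_basis(curve, grid) %*% curve$beta)
  if (any(!is.finite(val))) stop_config("non-finite curve values in MMT search")
  idx <- which(val <= min(val) + 1e-12)
  med <- curve$temp_percentiles[2]
  grid[idx[which.min(abs(grid[idx] - med))]]
}

#' Predict from a cumulative exposure-response curve
#'
#' Evaluates the cumulative log relative risk at arbitrary temperatures.
#' Inside the observed boundary this is the fitted natural spline; beyond the
#' boundary the natural spline continues linearly in log-RR (continuous with
#' continuous first derivative), which is the log-linear extrapolation used
#' when projection temperatures exceed the observed range.
#'
#' @param object a `cumcurve`.
#' @param temps numeric temperatures (degrees C).
#' @param cen centring temperature; defaults to the curve's MMT so that
#'   `logrr(cen) = 0`.
#' @param se logical; also return pointwise standard errors of the centred
#'   log-RR.
#' @param ... unused.
#' @return if `se = FALSE`, a numeric vector of centred log-RR; otherwise a
#'   data frame with `temp`, `logrr`, `se`, `rr`, `rr_low`, `rr_high`
#'   (pointwise 95 percent Wald limits).
#' @export
predict.cumcurve <- function(object, temps, cen = object$mmt, se = FALSE,
                             ...) {
  if (any(!is.finite(temps))) stop_config("non-finite temperatures")
  B <- curve_basis(object, temps)
  if (is.finite(cen)) {
    B <- B - matrix(curve_basis(object, cen), nrow(B), ncol(B), byrow = TRUE)
  }
  logrr <- drop(B %*% object$beta)
  if (!se) return(logrr)
  sev <- sqrt(pmax(0, rowSums((B %*% object$vcov) * B)))
  data.frame(temp = temps, logrr = logrr, se = sev, rr = exp(logrr),
             rr_low = exp(logrr - 1.96 * sev),
             rr_high = exp(logrr + 1.96 * sev))
}

#' @export
coef.cumcurve <- function(object, ...) object$beta

#' @export
vcov.cumcurve <- function(object, ...) object$vcov

#' @export
print.cumcurve <- function(x, ...) {
  cat(sprintf("Cumulative exposure-response curve (%s)\n", x$kind))
  cat(sprintf("  basis dim %d, boundary %.2f .. %.2f C, MMT %.1f C\n",
              length(x$beta), x$boundary[1], x$boundary[2], x$mmt))
  invisible(x)
}

#' Plot a cumulative exposure-response curve
#'
#' Relative risk against temperature with a pointwise 95 percent confidence
#' band, centred at the MMT.
#'
#' @param x a `cumcurve`.
#' @param from,to plotting range (defaults to the observed 1st-99th
#'   percentiles).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the prediction data frame.
#' @export
plot.cumcurve <- function(x, from = x$temp_percentiles[1],
                          to = x$temp_percentiles[3], ...) {
  grid <- seq(from, to, length.out = 200)
  pr <- predict(x, grid, se = TRUE)
  graphics::plot(grid, pr$rr, type = "n",
                 xlab = "Daily mean temperature (°C)",
                 ylab = "Relative risk",
                 ylim = range(pr$rr_low, pr$rr_high), ...)
  graphics::polygon(c(grid, rev(grid)), c(pr$rr_low, rev(pr$rr_high)),
                    col = grDevices::adjustcolor("firebrick", 0.2),
                    border = NA)
  graphics::lines(grid, pr$rr, col = "firebrick", lwd = 2)
  graphics::abline(h = 1, lty = 3)
  graphics::abline(v = x$mmt, lty = 2, col = "grey40")
  invisible(pr)
}

#' Serialize a cumulative curve to JSON
#'
#' @param curve a `cumcurve`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
curve_to_json <- function(curve, path = NULL) {
  doc <- list(
    schema = "heatmort/cumcurve/v1",
    kind = curve$kind,
    beta = curve$beta,
    vcov = curve$vcov,
    var_knots = curve$var_knots,
    boundary = curve$boundary,
    mmt = curve$mmt,
    phi = curve$phi,
    temp_percentiles = curve$temp_percentiles,
    spec = unclass(curve$spec)
  )
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a cumulative curve from JSON
#'
#' @param path file path or JSON string produced by [curve_to_json()].
#' @return a `cumcurve`.
#' @export
curve_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  spec <- basis_spec(doc$spec$var_knots_pct, doc$spec$lag_max,
                     doc$spec$n_lag_knots, doc$spec$lag_knot_scale)
  new_cumcurve(beta = doc$beta, vcov = as.matrix(doc$vcov),
               var_knots = doc$var_knots, boundary = doc$boundary,
               spec = spec, temp_percentiles = doc$temp_percentiles,
               phi = doc$phi, mmt = doc$mmt, kind = doc$kind)
}
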