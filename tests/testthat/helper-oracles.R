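# Shared fixtures and independent brute-force oracles.

tiny_config <- function(...) {
  defaults <- list(n_locations = 2, n_years = 3, n_models = 2,
                   overdispersion = 1, heterogeneity_sd = 0)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Brute-force cross-basis: explicit double sum over lags and basis functions,
# recomputed from the stored knots with scalar loops.
bf_crossbasis <- function(x, cb) {
  spec <- attr(cb, "spec")
  Bx <- unclass(splines::ns(x, knots = attr(cb, "var_knots"),
                            Boundary.knots = attr(cb, "boundary")))
  Bl <- attr(cb, "lag_basis")
  n <- length(x); vx <- ncol(Bx); vl <- ncol(Bl); L <- spec$lag_max
  out <- matrix(NA_real_, n, vx * vl)
  for (t in seq_len(n)) {
    if (t <= L) next
    col <- 0L
    for (j in seq_len(vx)) {
      for (k in seq_len(vl)) {
        col <- col + 1L
        acc <- 0
        for (l in 0:L) acc <- acc + Bx[t - l, j] * Bl[l + 1, k]
        out[t, col] <- acc
      }
    }
  }
  out
}

# Lag-specific log-RR at temperature temp from the full fitted surface,
# summed over lags (uncentred).
bf_cumulative_prediction <- function(fit, temp) {
  Bx <- unclass(splines::ns(temp, knots = fit$var_knots,
                            Boundary.knots = fit$boundary))
  Bl <- fit$lag_basis
  beta <- fit$coefficients[fit$cb_index]
  total <- 0
  for (l in 0:fit$spec$lag_max) {
    col <- 0L
    for (j in seq_len(fit$vx)) {
      for (k in seq_len(fit$vl)) {
        col <- col + 1L
        total <- total + beta[col] * Bx[1, j] * Bl[l + 1, k]
      }
    }
  }
  total
}

# Exhaustive scan for GWL crossing years: all 20-year windows, centred rule.
bf_gwl_crossing <- function(years, anomaly, level) {
  n <- length(years)
  for (c_idx in 10:(n - 10)) {
    if (mean(anomaly[(c_idx - 9):(c_idx + 10)]) >= level) {
      return(years[c_idx])
    }
  }
  NA_integer_
}

# A cumcurve built directly from known coefficients (bypasses fitting), for
# closed-form checks of MMT search, extrapolation and projection.
manual_curve <- function(beta, vcov = diag(0, length(beta)),
                         var_knots = c(10, 18, 24),
                         boundary = c(0, 32),
                         percentiles = c(2, 16, 30)) {
  crv <- heatmort:::new_cumcurve(
    beta = beta, vcov = vcov, var_knots = var_knots, boundary = boundary,
    spec = basis_spec(), temp_percentiles = percentiles, kind = "manual"
  )
  crv$mmt <- find_mmt(crv)
  crv
}

# Least-squares spline approximation of a target log-RR function, used to
# construct curves that track a known shape.
curve_from_function <- function(f, var_knots = c(10, 18, 24),
                                boundary = c(0, 32),
                                percentiles = c(2, 16, 30)) {
  g <- seq(boundary[1], boundary[2], length.out = 400)
  B <- unclass(splines::ns(g, knots = var_knots, Boundary.knots = boundary))
  # fit with an intercept (log-RR is identified up to a constant); only the
  # spline coefficients shape the curve
  beta <- qr.coef(qr(cbind(1, B)), f(g))[-1]
  manual_curve(beta, var_knots = var_knots, boundary = boundary,
               percentiles = percentiles)
}
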