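#' Specification of the exposure and lag bases
#'
#' Defines the bi-dimensional spline basis of a distributed lag non-linear
#' model: a natural cubic spline of temperature with internal knots at
#' percentiles of the observed distribution (default 10th, 75th and 90th,
#' boundary knots at the observed range, no intercept) crossed with a natural
#' cubic spline of lag 0..`lag_max` days with `n_lag_knots` internal knots
#' and an intercept.
#'
#' @param var_knots_pct percentiles (in (0,100), strictly increasing) of the
#'   temperature distribution at which exposure knots are placed.
#' @param lag_max maximum lag in days.
#' @param n_lag_knots number of internal lag knots.
#' @param lag_knot_scale `"log"` places the internal lag knots at equally
#'   spaced values of log-lag between lag 1 and `lag_max` (the convention of
#'   the standard DLNM software, concentrating flexibility at short lags);
#'   `"linear"` spaces them equally on the lag scale.
#' @return list of class `basis_spec`.
#' @examples
#' basis_spec()
#' @export
basis_spec <- function(var_knots_pct = c(10, 75, 90),
                       lag_max = 21L,
                       n_lag_knots = 3L,
                       lag_knot_scale = c("log", "linear")) {
  lag_knot_scale <- match.arg(lag_knot_scale)
  if (any(diff(var_knots_pct) <= 0) ||
      any(var_knots_pct <= 0) || any(var_knots_pct >= 100)) {
    stop_config("var_knots_pct must be strictly increasing within (0, 100)")
  }
  if (!is_count(lag_max)) stop_config("lag_max must be a count >= 1")
  if (!is_count(n_lag_knots) || n_lag_knots >= lag_max) {
    stop_config("n_lag_knots must be a count interior to (0, lag_max)")
  }
  out <- list(var_knots_pct = var_knots_pct, lag_max = as.integer(lag_max),
              n_lag_knots = as.integer(n_lag_knots),
              lag_knot_scale = lag_knot_scale)
  class(out) <- "basis_spec"
  out
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("DLNM basis specification\n")
  cat("  exposure: natural cubic spline, knots at percentiles",
      paste(x$var_knots_pct, collapse = ", "), "\n")
  cat(sprintf("  lag: natural cubic spline over 0..%d days, %d internal knots (%s scale), intercept\n",
              x$lag_max, x$n_lag_knots, x$lag_knot_scale))
  invisible(x)
}

lag_knot_values <- function(spec) {
  if (spec$lag_knot_scale == "log") {
    exp(seq(log(1), log(spec$lag_max), length.out = spec$n_lag_knots + 2L))[
      2:(spec$n_lag_knots + 1L)]
  } else {
    seq(0, spec$lag_max, length.out = spec$n_lag_knots + 2L)[
      2:(spec$n_lag_knots + 1L)]
  }
}

lag_basis <- function(spec) {
  unclass(ns_eval(0:spec$lag_max, knots = lag_knot_values(spec),
                  boundary = c(0, spec$lag_max), intercept = TRUE))
}

exposure_knots <- function(x, spec) {
  stats::quantile(x, spec$var_knots_pct / 100, na.rm = TRUE, names = FALSE)
}

#' Build the DLNM cross-basis of a daily temperature series
#'
#' Constructs the design matrix whose column `(j, k)` at day `t` is the
#' finite convolution `sum_{l=0}^{L} Bx_j(T[t-l]) * Bl_k(l)` of the exposure
#' basis evaluated at lagged temperatures with the lag basis. Rows whose lag
#' window extends before the series start (the first `lag_max` rows) carry
#' incomplete lag information and are set to `NA`, as is any row whose lag
#' window covers a missing temperature; such rows drop out of the likelihood.
#'
#' @param x numeric daily mean temperature series (degrees C), in time order.
#' @param spec a [basis_spec()].
#' @return an `n x (v_x * v_l)` matrix of class `crossbasis` with attributes
#'   `spec`, `var_knots`, `boundary`, `lag_basis`, `vx`, `vl`. Columns are
#'   ordered exposure-major (`cb.j.k`, lag index fastest).
#' @examples
#' x <- 15 + 8 * sin(seq(0, 4 * pi, length.out = 400))
#' cb <- crossbasis(x)
#' dim(cb)
#' @export
crossbasis <- function(x, spec = basis_spec()) {
  if (length(x) <= spec$lag_max) {
    stop_config("series must be longer than lag_max (%d days)", spec$lag_max)
  }
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || diff(rng) < sqrt(.Machine$double.eps)) {
    stop_config("degenerate temperature series: knots are not computable")
  }
  knots <- exposure_knots(x, spec)
  if (any(diff(knots) <= 0)) {
    stop_config("degenerate temperature series: percentile knots coincide")
  }
  Bx <- unclass(ns_eval(x, knots = knots, boundary = rng))
  Bl <- lag_basis(spec)
  n <- length(x); vx <- ncol(Bx); vl <- ncol(Bl); L <- spec$lag_max
  cb <- matrix(0, n, vx * vl)
  jrep <- rep(seq_len(vx), each = vl)
  krep <- rep(seq_len(vl), times = vx)
  for (l in 0:L) {
    Xl <- rbind(matrix(NA_real_, l, vx),
                Bx[seq_len(n - l), , drop = FALSE])
    cb <- cb + Xl[, jrep, drop = FALSE] *
      matrix(Bl[l + 1L, krep], n, vx * vl, byrow = TRUE)
  }
  colnames(cb) <- sprintf("cb.%d.%d", jrep, krep)
  structure(cb, class = c("crossbasis", "matrix"),
            spec = spec, var_knots = knots, boundary = rng,
            lag_basis = Bl, vx = vx, vl = vl)
}

#' @export
print.crossbasis <- function(x, ...) {
  cat(sprintf("crossbasis: %d days x %d terms (vx = %d, vl = %d)\n",
              nrow(x), ncol(x), attr(x, "vx"), attr(x, "vl")))
  cat("  exposure knots:",
      paste(formatC(attr(x, "var_knots"), digits = 4, format = "g"),
            collapse = ", "),
      " boundary:", paste(formatC(attr(x, "boundary"), digits = 4,
                                  format = "g"), collapse = " .. "), "\n")
  invisible(x)
}
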