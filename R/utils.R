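# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages draw from sub-streams derived from one master seed by
#' a fixed counter scheme, so that e.g. adding a climate model never perturbs
#' the series already generated for earlier models or locations.
#'
#' @param seed master integer seed.
#' @param stream character stream label (e.g. `"temperature"`, `"model"`).
#' @param index,index2 integer counters (location id, model id, replicate...).
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, stream, index = 0L, index2 = 0L) {
  codes <- c(
    temperature = 1, mortality = 2, heterogeneity = 3, model = 4,
    anomaly = 5, covid = 6, metadata = 7, montecarlo = 8, pipeline = 9
  )
  if (!stream %in% names(codes)) {
    stop("unknown sub-stream label: ", stream)
  }
  s <- (abs(as.numeric(seed)) %% 1e6) * 7 +
    codes[[stream]] * 1000003 +
    as.numeric(index) * 10007 +
    as.numeric(index2) * 2971
  as.integer(s %% 2147483645) + 1L
}

# Natural cubic spline basis evaluated with frozen knots; linear beyond the
# boundary knots by construction (the extrapolation rule the projection
# module relies on).
ns_eval <- function(x, knots, boundary, intercept = FALSE) {
  splines::ns(x, knots = knots, Boundary.knots = boundary,
              intercept = intercept)
}

# Day-of-year as a fraction for seasonal terms; locale-independent.
day_of_year <- function(dates) {
  as.POSIXlt(dates)$yday + 1
}

day_of_week <- function(dates) {
  factor(format(dates, "%u"), levels = as.character(1:7))
}

years_spanned <- function(dates) {
  length(dates) / 365.25
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
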