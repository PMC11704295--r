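#' Global-warming-level windows per climate model
#'
#' For each model and warming level, finds the first year at which the
#' centred 20-year running mean of the model's annual global-mean anomaly
#' (relative to 1850-1900) reaches the level; the GWL window is the 20-year
#' period centred there (`crossing_year - 9` to `crossing_year + 10`). Models
#' that never reach a level contribute no window for it (with a warning).
#' Windows are defined per model, so models with different climate
#' sensitivities realise the same level in different periods.
#'
#' @param anomaly data frame with columns `model_id`, `year`, `anomaly`.
#' @param levels warming levels in degrees C (default 1.0, 1.5, 2.0, 3.0).
#' @param variant `"centered"` (default, as above) or `"first-crossing-start"`
#'   (window starts at the crossing year).
#' @return data frame with columns `model_id`, `level`, `crossing_year`,
#'   `start_year`, `end_year` (inclusive, spanning 20 years).
#' @examples
#' an <- data.frame(model_id = 1, year = 1:100, anomaly = 0.03 * (1:100))
#' gwl_windows(an, levels = 1.5)
#' @export
gwl_windows <- function(anomaly, levels = c(1, 1.5, 2, 3),
                        variant = c("centered", "first-crossing-start")) {
  variant <- match.arg(variant)
  stopifnot(all(c("model_id", "year", "anomaly") %in% names(anomaly)))
  if (any(diff(sort(levels)) <= 0) && length(levels) > 1) {
    stop_config("levels must be distinct")
  }
  out <- list()
  for (m in unique(anomaly$model_id)) {
    am <- anomaly[anomaly$model_id == m, ]
    am <- am[order(am$year), ]
    n <- nrow(am)
    if (n < 20) stop_config("anomaly series for model %s shorter than 20 years", m)
    # running mean of the 20-year window centred at index i: years i-9..i+10
    cums <- cumsum(c(0, am$anomaly))
    centers <- 10:(n - 10)
    rmean <- (cums[centers + 11] - cums[centers - 9]) / 20
    for (lev in sort(levels)) {
      hit <- which(rmean >= lev)
      if (!length(hit)) {
        warning(sprintf("model %s never reaches +%.1f C; no window", m, lev),
                call. = FALSE)
        next
      }
      cy <- am$year[centers[hit[1]]]
      if (variant == "centered") {
        sy <- cy - 9L
      } else {
        sy <- cy
      }
      out[[length(out) + 1L]] <- data.frame(
        model_id = m, level = lev, crossing_year = cy,
        start_year = sy, end_year = sy + 19L
      )
    }
  }
  if (!length(out)) {
    return(data.frame(model_id = character(0), level = numeric(0),
                      crossing_year = integer(0), start_year = integer(0),
                      end_year = integer(0)))
  }
  do.call(rbind, out)
}

#' Calibrate an empirical quantile-mapping bias correction
#'
#' Maps the empirical quantiles of a climate model's daily temperatures onto
#' the station's over a common calibration period, at `n_q` equally spaced
#' probabilities (default 1..99 percent). Between fitted quantiles the
#' correction interpolates linearly; beyond the outermost quantiles a
#' constant offset (the correction at that quantile) applies, avoiding
#' unbounded extrapolation. By default twelve separate maps are fitted, one
#' per calendar month, so the seasonal structure of the bias is corrected.
#'
#' @param model_daily data frame `date`, `tmean` of the model over the
#'   calibration period (rows outside `station_daily`'s dates are ignored).
#' @param station_daily data frame `date`, `tmean` of station observations.
#' @param n_q number of quantiles.
#' @param by_month logical; fit one map per calendar month (default) or a
#'   single annual map.
#' @return object of class `quantile_map`. Methods: `print`,
#'   [predict.quantile_map()].
#' @export
quantile_map <- function(model_daily, station_daily, n_q = 99,
                         by_month = TRUE) {
  stopifnot(all(c("date", "tmean") %in% names(model_daily)),
            all(c("date", "tmean") %in% names(station_daily)))
  common <- as.Date(intersect(as.numeric(model_daily$date),
                              as.numeric(station_daily$date)))
  if (length(common) < 365) {
    stop_config("calibration overlap must cover at least one year (got %d days)",
                length(common))
  }
  md <- model_daily[model_daily$date %in% common, ]
  sd_ <- station_daily[station_daily$date %in% common, ]
  probs <- seq_len(n_q) / (n_q + 1)
  # type-1 (inverse empirical CDF) quantiles are actual sample values, which
  # makes the calibration closure exact: the corrected model quantile at each
  # fitted probability reproduces the station quantile.
  fit_one <- function(mv, sv) {
    mq <- stats::quantile(mv, probs, names = FALSE, na.rm = TRUE, type = 1)
    sq <- stats::quantile(sv, probs, names = FALSE, na.rm = TRUE, type = 1)
    # collapse duplicated model quantiles (possible with discretised data)
    keep <- !duplicated(mq)
    list(mq = mq[keep], sq = sq[keep])
  }
  months <- if (by_month) 1:12 else 0L
  maps <- lapply(months, function(mo) {
    if (mo == 0L) {
      fit_one(md$tmean, sd_$tmean)
    } else {
      sel_m <- as.POSIXlt(md$date)$mon + 1 == mo
      sel_s <- as.POSIXlt(sd_$date)$mon + 1 == mo
      fit_one(md$tmean[sel_m], sd_$tmean[sel_s])
    }
  })
  structure(list(maps = maps, by_month = by_month, n_q = n_q, probs = probs,
                 calibration_range = range(common)),
            class = "quantile_map")
}

#' @export
print.quantile_map <- function(x, ...) {
  cat(sprintf("Quantile-mapping bias correction: %d quantiles, %s\n",
              x$n_q, if (x$by_month) "12 monthly maps" else "one annual map"))
  cat("  calibrated on",
      paste(format(x$calibration_range), collapse = " .. "), "\n")
  invisible(x)
}

apply_one_map <- function(map, v) {
  mq <- map$mq; sq <- map$sq
  out <- numeric(length(v))
  lo <- v < mq[1]; hi <- v > mq[length(mq)]
  mid <- !lo & !hi
  if (any(mid)) {
    out[mid] <- stats::approx(mq, sq, xout = v[mid], ties = "ordered")$y
  }
  # constant tail offset: difference at the outermost fitted quantile
  out[lo] <- v[lo] + (sq[1] - mq[1])
  out[hi] <- v[hi] + (sq[length(sq)] - mq[length(mq)])
  out
}

#' Apply a quantile-mapping bias correction
#'
#' The fitted map is monotone non-decreasing, so the corrected series
#' preserves the rank order of the model series.
#'
#' @param object a [quantile_map()].
#' @param newdata data frame with columns `date`, `tmean` (dates are needed
#'   for monthly maps), or a numeric vector when the map is annual.
#' @param ... unused.
#' @return corrected temperatures, same length and order as the input.
#' @export
predict.quantile_map <- function(object, newdata, ...) {
  if (is.numeric(newdata)) {
    if (object$by_month) {
      stop_config("monthly quantile map needs dates; pass a date/tmean data frame")
    }
    return(apply_one_map(object$maps[[1]], newdata))
  }
  stopifnot(all(c("date", "tmean") %in% names(newdata)))
  if (!object$by_month) {
    return(apply_one_map(object$maps[[1]], newdata$tmean))
  }
  out <- numeric(nrow(newdata))
  mo <- as.POSIXlt(newdata$date)$mon + 1
  for (m in 1:12) {
    sel <- mo == m
    if (any(sel)) out[sel] <- apply_one_map(object$maps[[m]],
                                            newdata$tmean[sel])
  }
  out
}

#' Extract the grid cell nearest to a location
#'
#' Selects, from a long-format grid table, the series of the grid point
#' minimising the great-circle distance to the location; exact ties are
#' broken by (lat, lon) lexicographic order so the result is deterministic.
#'
#' @param grid data frame with columns `lon`, `lat` and the series columns
#'   (e.g. `model_id`, `date`, `tmean`).
#' @param lon,lat location coordinates in degrees.
#' @return the rows of `grid` belonging to the nearest grid point.
#' @export
extract_nearest_gridcell <- function(grid, lon, lat) {
  stopifnot(all(c("lon", "lat") %in% names(grid)))
  if (!nrow(grid)) stop_config("empty grid")
  pts <- unique(grid[, c("lon", "lat")])
  d <- geosphere::distHaversine(as.matrix(pts), c(lon, lat))
  best <- d <= min(d) + 1e-6
  cand <- pts[best, , drop = FALSE]
  cand <- cand[order(cand$lat, cand$lon), , drop = FALSE]
  sel <- grid$lon == cand$lon[1] & grid$lat == cand$lat[1]
  grid[sel, , drop = FALSE]
}

#' Bias-corrected daily temperatures inside each GWL window
#'
#' Convenience assembling step: calibrates a quantile map of a model against
#' the station record and returns corrected daily series restricted to each
#' of the model's GWL windows.
#'
#' @param model_daily data frame `date`, `tmean` for one model at the
#'   location.
#' @param station_daily observed data frame `date`, `tmean`.
#' @param windows the model's rows of a [gwl_windows()] table.
#' @param ... passed to [quantile_map()].
#' @return named list (by `level`) of corrected temperature vectors; windows
#'   not fully covered by the model series are dropped with a warning.
#' @export
corrected_window_temps <- function(model_daily, station_daily, windows, ...) {
  qm <- quantile_map(model_daily, station_daily, ...)
  yrs <- as.POSIXlt(model_daily$date)$year + 1900
  out <- list()
  for (r in seq_len(nrow(windows))) {
    sel <- yrs >= windows$start_year[r] & yrs <= windows$end_year[r]
    n_expected <- length(seq(as.Date(sprintf("%d-01-01", windows$start_year[r])),
                             as.Date(sprintf("%d-12-31", windows$end_year[r])),
                             by = "day"))
    if (sum(sel) < n_expected) {
      warning(sprintf("model %s: +%.1f C window %d-%d not fully covered; dropped",
                      windows$model_id[r], windows$level[r],
                      windows$start_year[r], windows$end_year[r]),
              call. = FALSE)
      next
    }
    out[[as.character(windows$level[r])]] <-
      predict(qm, model_daily[sel, c("date", "tmean")])
  }
  out
}
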