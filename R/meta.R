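#' Multivariate random-effects meta-regression by REML
#'
#' Estimation engine for the second stage: outcomes `y_i` (one row per
#' location, e.g. reduced curve coefficients) are modelled as
#' `y_i ~ N(Theta' x_i, Psi + V_i)` with known within-location covariances
#' `V_i`, unknown between-location covariance `Psi` and fixed-effect matrix
#' `Theta`. `Psi` is parameterised through its Cholesky factor (log-diagonal)
#' and the REML objective, with the fixed effects profiled out by generalized
#' least squares, is maximised by BFGS.
#'
#' @param y numeric matrix, `n_locations x p`, of outcome vectors.
#' @param V list of `p x p` within-location covariance matrices.
#' @param X design matrix `n_locations x q` of meta-predictors (including
#'   the intercept column).
#' @param control list; `reltol` and `maxit` are passed to [stats::optim()].
#' @return list of class `meta_reml`: `theta` (`q x p` fixed effects),
#'   `vcov_theta` (covariance of `vec(theta)` stacked outcome-major), `psi`,
#'   `loglik` (restricted), `converged`, plus the inputs.
#' @examples
#' y <- cbind(c(0.1, 0.2, 0.15, 0.3))
#' V <- rep(list(matrix(0.01)), 4)
#' fit <- meta_reml(y, V, matrix(1, 4, 1))
#' fit$theta
#' @export
meta_reml <- function(y, V, X, control = list()) {
  y <- as.matrix(y)
  n <- nrow(y); p <- ncol(y); q <- ncol(X)
  stopifnot(length(V) == n, nrow(X) == n)
  if (n < max(q + 1L, 3L)) {
    stop_config("need at least max(q + 1, 3) = %d locations, got %d",
                max(q + 1L, 3L), n)
  }
  qrX <- qr(X)
  if (qrX$rank < q) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):q]]
    stop_config("singular meta-regression design; collinear columns: %s",
                paste(bad, collapse = ", "))
  }
  U <- lapply(seq_len(n), function(i) kronecker(diag(p), t(X[i, ])))

  gls_pieces <- function(W) {
    A <- matrix(0, p * q, p * q)
    b <- numeric(p * q)
    for (i in seq_len(n)) {
      WU <- W[[i]] %*% U[[i]]
      A <- A + crossprod(U[[i]], WU)
      b <- b + drop(crossprod(WU, y[i, ]))
    }
    theta <- solve(A, b)
    list(A = A, theta = theta)
  }

  neg2reml <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    Psi <- chol_expand(par, p)
    logdet_sum <- 0
    W <- vector("list", n)
    for (i in seq_len(n)) {
      S <- Psi + V[[i]]
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      logdet_sum <- logdet_sum + 2 * sum(log(diag(ch)))
      W[[i]] <- chol2inv(ch)
    }
    g <- tryCatch(gls_pieces(W), error = function(e) NULL)
    if (is.null(g)) return(1e10)
    quad <- 0
    for (i in seq_len(n)) {
      r <- y[i, ] - drop(U[[i]] %*% g$theta)
      quad <- quad + drop(crossprod(r, W[[i]] %*% r))
    }
    ldA <- determinant(g$A, logarithm = TRUE)$modulus
    logdet_sum + as.numeric(ldA) + quad
  }

  Vbar <- Reduce(`+`, V) / n
  psi0 <- 0.1 * Vbar
  par0 <- chol_collapse(psi0 + diag(1e-8, p), p)
  ctl <- list(reltol = control$reltol %||% 1e-10,
              maxit = control$maxit %||% 500)
  opt <- stats::optim(par0, neg2reml, method = "BFGS",
                      control = list(reltol = ctl$reltol, maxit = ctl$maxit))
  Psi <- chol_expand(opt$par, p)
  W <- lapply(seq_len(n), function(i) chol2inv(chol(Psi + V[[i]])))
  g <- gls_pieces(W)
  # g$theta is stacked in p blocks of length q (one block per outcome,
  # because U_i = I_p (x) x_i'), so column-filling gives theta as q x p.
  theta <- matrix(g$theta, nrow = q)
  structure(list(theta = theta, vcov_theta = solve(g$A), psi = Psi,
                 loglik = -0.5 * opt$value, converged = opt$convergence == 0,
                 objective_init = -0.5 * neg2reml(par0),
                 y = y, V = V, X = X, U = U),
            class = "meta_reml")
}

# Lower-triangular Cholesky parameterisation with log-diagonal, so any real
# parameter vector maps to a PSD matrix.
chol_expand <- function(par, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

chol_collapse <- function(Psi, p) {
  L <- t(chol(Psi))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

#' @export
print.meta_reml <- function(x, ...) {
  cat(sprintf("Multivariate REML meta-regression: %d locations, %d outcomes, %d predictors\n",
              nrow(x$y), ncol(x$y), ncol(x$X)))
  cat(sprintf("  restricted log-likelihood %.3f (converged: %s)\n",
              x$loglik, x$converged))
  cat("  between-location sd:",
      paste(formatC(sqrt(diag(x$psi)), digits = 3, format = "g"),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pool first-stage curves by multivariate meta-regression
#'
#' Second stage of the two-stage design: reduced cumulative-curve
#' coefficients from all locations are pooled in a multivariate
#' random-effects meta-regression, optionally conditioning on location-level
#' meta-predictors (region and climate-class indicators, log GDP per capita,
#' mean and range of observed temperature). Numeric predictors are
#' standardized internally for conditioning; the returned fixed effects are
#' on the standardized scale, and predictions handle the scaling.
#'
#' @param curves list of `cumcurve` objects sharing one [basis_spec()].
#' @param formula meta-predictor formula (default intercept-only pooling).
#' @param data data frame of meta-predictors, one row per curve, required
#'   when `formula` involves variables.
#' @param control passed to [meta_reml()].
#' @return object of class `heat_meta` wrapping the [meta_reml()] fit plus
#'   curve metadata. Methods: `print`, `coef`, [blup()].
#' @examples
#' cfg <- sim_config(n_locations = 3, n_years = 2, n_models = 1,
#'                   overdispersion = 1)
#' curves <- lapply(1:3, function(i)
#'   cumulative_curve(heat_dlnm(simulate_mortality(cfg, i))))
#' pooled <- heat_meta(curves)
#' pooled
#' @export
heat_meta <- function(curves, formula = ~1, data = NULL, control = list()) {
  stopifnot(length(curves) >= 2, all(vapply(curves, inherits, TRUE,
                                            "cumcurve")))
  specs <- lapply(curves, function(cr) unclass(cr$spec))
  if (!all(vapply(specs, identical, TRUE, specs[[1]]))) {
    stop_config("all curves must share one basis specification")
  }
  n <- length(curves)
  if (is.null(data)) data <- data.frame(row.names = seq_len(n))
  X <- stats::model.matrix(formula, data)
  scaling <- NULL
  num <- setdiff(colnames(X), "(Intercept)")
  num <- num[vapply(num, function(cn) length(unique(X[, cn])) > 2, TRUE)]
  if (length(num)) {
    ctr <- colMeans(X[, num, drop = FALSE])
    scl <- apply(X[, num, drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    X[, num] <- sweep(sweep(X[, num, drop = FALSE], 2, ctr), 2, scl, "/")
    scaling <- list(columns = num, center = ctr, scale = scl)
  }
  y <- t(vapply(curves, function(cr) cr$beta, numeric(length(curves[[1]]$beta))))
  V <- lapply(curves, function(cr) cr$vcov)
  fit <- meta_reml(y, V, X, control)
  structure(list(meta = fit, curves = curves, formula = formula,
                 scaling = scaling, X = X),
            class = "heat_meta")
}

#' @export
print.heat_meta <- function(x, ...) {
  cat("Second-stage pooling of cumulative curves\n")
  print(x$meta)
  invisible(x)
}

#' @export
coef.heat_meta <- function(object, ...) object$meta$theta

#' Best linear unbiased predictions
#'
#' @param object a fitted model supporting BLUP extraction.
#' @param ... method arguments.
#' @export
blup <- function(object, ...) UseMethod("blup")

# Posterior (BLUP) coefficients and covariance for one location.
blup_one <- function(theta_vec, vcov_theta, Psi, Vi, yi, Ui) {
  W <- solve(Psi + Vi)
  mu <- drop(Ui %*% theta_vec)
  shrink <- Psi %*% W
  b <- mu + drop(shrink %*% (yi - mu))
  A <- (diag(nrow(Psi)) - shrink) %*% Ui
  Vb <- Psi - shrink %*% Psi + A %*% vcov_theta %*% t(A)
  list(beta = b, vcov = (Vb + t(Vb)) / 2)
}

#' Location-specific BLUP curves from a pooled model
#'
#' Shrinks each location's reduced curve toward the meta-regression
#' prediction, weighting by the between- versus within-location covariance:
#' `beta_blup_i = X_i Theta + Psi (Psi + V_i)^-1 (beta_i - X_i Theta)`. The
#' BLUP covariance accounts for fixed-effect uncertainty, and the MMT is
#' re-found on each BLUP curve.
#'
#' @param object a [heat_meta()] fit.
#' @param ... unused.
#' @return list of `cumcurve` objects (kind `"blup"`), one per location.
#' @export
blup.heat_meta <- function(object, ...) {
  m <- object$meta
  if (!m$converged) stop_config("meta-regression did not converge")
  theta_vec <- as.numeric(m$theta)  # p blocks of length q, outcome-major
  lapply(seq_along(object$curves), function(i) {
    cr <- object$curves[[i]]
    bl <- blup_one(theta_vec, m$vcov_theta, m$psi, m$V[[i]], m$y[i, ],
                   m$U[[i]])
    out <- new_cumcurve(beta = bl$beta, vcov = bl$vcov,
                        var_knots = cr$var_knots, boundary = cr$boundary,
                        spec = cr$spec,
                        temp_percentiles = cr$temp_percentiles,
                        phi = cr$phi, kind = "blup")
    out$mmt <- find_mmt(out)
    out
  })
}

#' Serialize a pooled model and its BLUPs to JSON
#'
#' @param object a [heat_meta()] fit.
#' @param path optional file path.
#' @return the JSON string, invisibly when written.
#' @export
meta_to_json <- function(object, path = NULL) {
  doc <- list(
    schema = "heatmort/meta/v1",
    theta = object$meta$theta,
    psi = object$meta$psi,
    loglik = object$meta$loglik,
    blups = lapply(blup(object), function(cr)
      jsonlite::fromJSON(curve_to_json(cr)))
  )
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
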