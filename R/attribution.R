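# Range-filtered, MMT-centred cumulative crossbasis for attribution: row t
# is sum over lags l of  I(x_{t-l} in range) (Bx(x_{t-l}) - Bx(mmt)) x Bl(l),
# so that row %*% beta is the backward cumulative log-RR contributed by the
# requested exposure range over the 21 preceding days.
af_matrix <- function(cb, mmt, range = c("all", "cold", "heat")) {
  range <- match.arg(range)
  series <- attr(cb, "series")
  es <- attr(cb, "exposure_spec")
  max_lag <- attr(cb, "max_lag")
  x <- series$tapp_c
  n <- length(x)
  ok <- !is.na(x)
  vx <- attr(cb, "vx")
  dbx <- matrix(0, n, vx)
  bc <- ns_basis(mmt, es)[1L, ]
  if (any(ok)) dbx[ok, ] <- sweep(ns_basis(x[ok], es), 2L, bc, "-")
  inrange <- switch(range,
                    all = ok,
                    cold = ok & x < mmt,
                    heat = ok & x > mmt)
  dbx[!inrange, ] <- 0
  bl <- ns_basis(0:max_lag, attr(cb, "lag_spec"))
  vl <- ncol(bl)
  jx <- rep(seq_len(vx), each = vl)
  jl <- rep(seq_len(vl), times = vx)
  m <- matrix(0, n, vx * vl)
  for (l in 0:max_lag) {
    shifted <- rbind(matrix(0, l, vx), dbx[seq_len(n - l), , drop = FALSE])
    m <- m + shifted[, jx, drop = FALSE] *
      matrix(bl[l + 1L, jl], n, vx * vl, byrow = TRUE)
  }
  m[match(attr(cb, "dates"), series$date), , drop = FALSE]
}

align_deaths <- function(cb, daily_deaths) {
  idx <- match(attr(cb, "dates"), as.Date(daily_deaths$date))
  keep <- which(!is.na(idx))
  if (!length(keep)) stop("no death days align with the crossbasis rows")
  list(keep = keep, deaths = daily_deaths$deaths[idx[keep]])
}

#' Backward-perspective attributable number and fraction
#'
#' For each day t with a complete lag history, the fraction of that day's
#' deaths attributable to the requested exposure range is
#' \deqn{1 - e^{-\sum_{l=0}^{L} \eta(x_{t-l},\, l)}}
#' where \eqn{\eta} is the per-lag log relative risk relative to the MMT,
#' with terms zeroed when the lagged exposure falls outside the range
#' (cold: strictly below the MMT; heat: strictly above; a day exactly at
#' the MMT contributes to neither). The attributable number is the sum of
#' those per-day fractions times the day's deaths; the attributable
#' fraction divides by total deaths over the same days. Days lacking a
#' full lag history are excluded from numerator and denominator alike.
#'
#' @param fit A converged `cc_fit`.
#' @param cb A `crossbasis` built with `event_days = NULL`.
#' @param daily_deaths Data frame with columns `date`, `deaths`.
#' @param mmt Reference (minimum-mortality) temperature, deg C.
#' @param range `"all"`, `"cold"` or `"heat"`.
#' @return List with `an`, `af`, `n_days`, `total_deaths`.
#' @export
attributable <- function(fit, cb, daily_deaths, mmt,
                         range = c("all", "cold", "heat")) {
  range <- match.arg(range)
  if (!isTRUE(fit$converged)) stop("attributable: non-converged fit")
  al <- align_deaths(cb, daily_deaths)
  m <- af_matrix(cb, mmt, range)[al$keep, , drop = FALSE]
  frac <- 1 - exp(-as.numeric(m %*% fit$beta))
  tot <- sum(al$deaths)
  an <- sum(frac * al$deaths)
  list(an = an, af = an / tot, n_days = length(al$keep), total_deaths = tot)
}

# symmetric square root of a covariance matrix (eigendecomposition);
# negative eigenvalues beyond tol are an error, small ones are clipped
psd_sqrt <- function(v, tol = 1e-8) {
  v <- (v + t(v)) / 2
  e <- eigen(v, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("covariance matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Monte Carlo empirical confidence intervals for attributable fractions
#'
#' Draws coefficient vectors from a multivariate normal centred at the
#' fitted coefficients with the fit covariance (via its symmetric matrix
#' square root applied to standard normals), recomputes the total, cold
#' and heat attributable fractions for each draw with the MMT held fixed
#' at its point estimate, and returns the 2.5th and 97.5th empirical
#' percentiles.
#'
#' @inheritParams attributable
#' @param n_replicates Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed; fixed seeds give bit-identical intervals.
#' @param keep_draws Return the per-draw AF matrix (for audit)?
#' @return List with per-component `ci` (2.5/97.5 percentiles of af and
#'   an), `n_replicates`, `seed`, and optionally `draws`.
#' @export
monte_carlo_ci <- function(fit, cb, daily_deaths, mmt,
                           n_replicates = 1000L, seed = 1L,
                           keep_draws = FALSE) {
  al <- align_deaths(cb, daily_deaths)
  tot <- sum(al$deaths)
  ms <- lapply(c(all = "all", cold = "cold", heat = "heat"),
               function(r) af_matrix(cb, mmt, r)[al$keep, , drop = FALSE])
  rt <- psd_sqrt(fit$vcov)
  p <- length(fit$beta)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(p * n_replicates), p, n_replicates)
  draws <- fit$beta + rt %*% z
  af_draw <- vapply(ms, function(m) {
    cum <- m %*% draws
    colSums((1 - exp(-cum)) * al$deaths) / tot
  }, numeric(n_replicates))
  ci <- lapply(stats::setNames(colnames(af_draw), colnames(af_draw)),
               function(cmp) {
                 q <- stats::quantile(af_draw[, cmp], c(0.025, 0.975),
                                      names = FALSE)
                 list(af_low = q[1L], af_high = q[2L],
                      an_low = q[1L] * tot, an_high = q[2L] * tot)
               })
  out <- list(ci = ci, n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  if (keep_draws) out$draws <- af_draw
  out
}

#' Full attribution summary with Monte Carlo intervals
#'
#' Point estimates of total, cold and heat attributable numbers and
#' fractions plus their Monte Carlo empirical 95% intervals, in one
#' object.
#'
#' @inheritParams monte_carlo_ci
#' @return An `attribution_result` list: `af_total`, `af_cold`,
#'   `af_heat`, `an_total`, `an_cold`, `an_heat`, `ci` (per component),
#'   `n_days`, `total_deaths`, `n_replicates`, `seed`, `mmt`.
#' @export
attribution <- function(fit, cb, daily_deaths, mmt,
                        n_replicates = 1000L, seed = 1L,
                        keep_draws = FALSE) {
  pt <- lapply(c(all = "all", cold = "cold", heat = "heat"),
               function(r) attributable(fit, cb, daily_deaths, mmt, r))
  mc <- monte_carlo_ci(fit, cb, daily_deaths, mmt,
                       n_replicates = n_replicates, seed = seed,
                       keep_draws = keep_draws)
  structure(list(af_total = pt$all$af, af_cold = pt$cold$af,
                 af_heat = pt$heat$af,
                 an_total = pt$all$an, an_cold = pt$cold$an,
                 an_heat = pt$heat$an,
                 ci = mc$ci, draws = mc$draws,
                 n_days = pt$all$n_days, total_deaths = pt$all$total_deaths,
                 n_replicates = mc$n_replicates, seed = mc$seed, mmt = mmt),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  fmt <- function(af, ci)
    sprintf("%5.1f%% (95%% CI %.1f, %.1f)", 100 * af,
            100 * ci$af_low, 100 * ci$af_high)
  cat("Attributable fraction relative to MMT", sprintf("%.1f C", x$mmt), "\n")
  cat("  total:", fmt(x$af_total, x$ci$all), "\n")
  cat("  cold :", fmt(x$af_cold, x$ci$cold), "\n")
  cat("  heat :", fmt(x$af_heat, x$ci$heat), "\n")
  invisible(x)
}
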