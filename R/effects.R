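#' Locate the minimum-mortality temperature
#'
#' Evaluates the (uncentered) lag-cumulated exposure-response curve on a
#' fine grid and returns the exposure with the lowest associated risk —
#' the reference "optimal" temperature against which cold and heat are
#' defined. By default the search is restricted to the central 95% of the
#' observed exposure distribution, which protects the estimate from
#' spurious behaviour of the spline tails at the extremes; ties (and an
#' entirely flat curve, as when all coefficients are zero) resolve toward
#' the grid median.
#'
#' @param fit A converged `cc_fit`.
#' @param cb The `crossbasis` the fit used.
#' @param restrict Percentile pair (0-100) bounding the search; default
#'   `c(2.5, 97.5)`. Use `c(0, 100)` for a full-range search.
#' @param step Grid step in degrees Celsius (default 0.1).
#' @return An `mmt_result`: list with `mmt` (deg C), `mmt_percentile`
#'   (percent of the exposure distribution at or below the MMT) and
#'   `search_range`.
#' @export
find_mmt <- function(fit, cb, restrict = c(2.5, 97.5), step = 0.1) {
  if (!isTRUE(fit$converged))
    stop("find_mmt: refusing a non-converged fit")
  x <- attr(cb, "series")$tapp_c
  x <- x[!is.na(x)]
  lim <- stats::quantile(x, restrict / 100, names = FALSE)
  bk <- attr(cb, "exposure_spec")$boundary_knots
  lim <- c(max(lim[1L], bk[1L]), min(lim[2L], bk[2L]))
  grid <- seq(lim[1L], lim[2L], by = step)
  ctr <- grid[which.min(abs(grid - stats::median(x)))]
  cur <- predict_cumulative(fit, cb, grid, center = ctr)
  if (any(!is.finite(cur$logrr)))
    stop("find_mmt: non-finite curve predictions")
  lo <- min(cur$logrr)
  if (max(cur$logrr) - lo < 1e-12) {
    warning("find_mmt: flat cumulative curve; returning the grid median")
    mmt <- stats::median(grid)
  } else {
    cand <- which(cur$logrr <= lo + 1e-12)
    med <- stats::median(grid)
    mmt <- grid[cand[which.min(abs(grid[cand] - med))]]
  }
  structure(list(mmt = mmt,
                 mmt_percentile = 100 * mean(x <= mmt),
                 search_range = lim),
            class = "mmt_result")
}

#' @export
print.mmt_result <- function(x, ...) {
  cat(sprintf("MMT %.1f C (%.0fth percentile; searched [%.1f, %.1f])\n",
              x$mmt, x$mmt_percentile, x$search_range[1L], x$search_range[2L]))
  invisible(x)
}

rr_ci <- function(logrr, var) {
  neg <- var < 0
  if (any(var < -1e-8))
    stop("negative prediction variance beyond numerical tolerance")
  var[neg] <- 0
  se <- sqrt(var)
  data.frame(rr = exp(logrr),
             rr_low = exp(logrr - 1.96 * se),
             rr_high = exp(logrr + 1.96 * se))
}

#' Cumulative exposure-response curve with 95% CI
#'
#' Relative risks centred at `center` (RR = 1 exactly there) with Wald
#' intervals on the log scale, `exp(logRR +/- 1.96 SE)`.
#'
#' @param fit A converged `cc_fit`.
#' @param cb The fitted `crossbasis`.
#' @param center Centering exposure, typically the MMT.
#' @param grid Exposure grid; default covers the central 95% of the
#'   observed series at 0.1 C steps.
#' @param restrict Percentile pair used when `grid` is `NULL`.
#' @return A `curve_result` data frame
#'   `exposure_c, rr, rr_low, rr_high` with attribute `center`.
#' @export
cumulative_curve <- function(fit, cb, center, grid = NULL,
                             restrict = c(2.5, 97.5)) {
  if (!isTRUE(fit$converged)) stop("cumulative_curve: non-converged fit")
  if (is.null(grid)) {
    x <- attr(cb, "series")$tapp_c
    lim <- stats::quantile(x[!is.na(x)], restrict / 100, names = FALSE)
    grid <- seq(lim[1L], lim[2L], by = 0.1)
  }
  pr <- predict_cumulative(fit, cb, grid, center)
  out <- cbind(data.frame(exposure_c = grid), rr_ci(pr$logrr, pr$var))
  attr(out, "center") <- center
  class(out) <- c("curve_result", "data.frame")
  out
}

#' Lag-response curve at one exposure, with 95% CI
#'
#' @inheritParams cumulative_curve
#' @param at_exposure Exposure (deg C) at which to slice the surface,
#'   e.g. the 5th or 95th percentile of the series.
#' @return A `curve_result` data frame `lag_days, rr, rr_low, rr_high`.
#' @export
lag_curve <- function(fit, cb, at_exposure, center) {
  if (!isTRUE(fit$converged)) stop("lag_curve: non-converged fit")
  pr <- predict_lag(fit, cb, at_exposure, center)
  out <- cbind(data.frame(lag_days = pr$lag), rr_ci(pr$logrr, pr$var))
  attr(out, "center") <- center
  attr(out, "at_exposure") <- at_exposure
  class(out) <- c("curve_result", "data.frame")
  out
}

#' Write a curve to CSV
#' @param curve A `curve_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
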