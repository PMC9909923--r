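#' Specify a one-dimensional basis
#'
#' Describes the spline (or hinge) space used for either the exposure or
#' the lag dimension of a crossbasis.
#'
#' @param kind `"ns"` for a natural cubic spline (second derivative zero
#'   outside the boundary knots, linear tails), or `"linear-threshold"` for
#'   a piecewise-linear hinge basis.
#' @param internal_knots Numeric vector of internal knots, strictly
#'   increasing and strictly inside the boundary knots.
#' @param boundary_knots Length-2 numeric vector.
#' @param intercept Should the basis span constants? The lag basis carries
#'   an intercept (a constant-in-lag effect must be representable); the
#'   exposure basis does not (it is not identifiable under within-stratum
#'   conditioning).
#' @return A `basis_spec` object.
#' @export
basis_spec <- function(kind = c("ns", "linear-threshold"),
                       internal_knots, boundary_knots, intercept = FALSE) {
  kind <- match.arg(kind)
  internal_knots <- as.numeric(internal_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L || diff(boundary_knots) <= 0)
    stop("basis_spec: boundary_knots must be an increasing pair")
  if (length(internal_knots)) {
    if (is.unsorted(internal_knots, strictly = TRUE))
      stop("basis_spec: internal knots must be strictly increasing")
    if (min(internal_knots) <= boundary_knots[1L] ||
        max(internal_knots) >= boundary_knots[2L])
      stop("basis_spec: internal knots must lie strictly inside the boundary knots")
  }
  structure(list(kind = kind, internal_knots = internal_knots,
                 boundary_knots = boundary_knots, intercept = intercept),
            class = "basis_spec")
}

#' Evaluate a basis on a vector of values
#'
#' For `kind = "ns"` this is the natural cubic spline basis with the
#' spec's knots: dimension `length(internal_knots) + 1 + intercept`,
#' linear beyond the boundary knots. For `"linear-threshold"` the columns
#' are the identity and one hinge \eqn{(x - k)_+} per internal knot.
#'
#' @param x Numeric vector (finite).
#' @param spec A [basis_spec()].
#' @return A numeric matrix with `length(x)` rows.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (any(!is.finite(x)))
    stop("ns_basis: values must be finite")
  if (spec$kind == "ns") {
    b <- splines::ns(x, knots = spec$internal_knots,
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
    m <- matrix(as.numeric(b), nrow = length(x))
  } else {
    m <- cbind(x, vapply(spec$internal_knots,
                         function(k) pmax(x - k, 0), numeric(length(x))))
    if (spec$intercept) m <- cbind(1, m)
  }
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' Lag knots equally spaced on the log scale
#'
#' Internal knots for the lag dimension at
#' `max_lag ^ (k / (n_knots + 1))`, `k = 1..n_knots` — i.e. equally spaced
#' between `log(1)` and `log(max_lag)`. Boundary knots are handled
#' separately (lag 0 and `max_lag`).
#'
#' @param max_lag Maximum lag in days (>= 2).
#' @param n_knots Number of internal knots (>= 1), default 3.
#' @return Numeric vector of knot positions on the lag (day) scale.
#' @examples
#' default_lag_knots(21, 3) # ~ 2.14, 4.58, 9.82
#' @export
default_lag_knots <- function(max_lag, n_knots = 3L) {
  stopifnot(max_lag >= 2, n_knots >= 1)
  exp(seq_len(n_knots) / (n_knots + 1) * log(max_lag))
}

#' Default exposure basis for an apparent-temperature series
#'
#' Natural cubic spline with internal knots at given percentiles of the
#' whole observed series (default 25th and 75th) and boundary knots at the
#' observed range.
#'
#' @param tapp A `tapp_series` (or numeric vector of exposures).
#' @param knot_percentiles Percentiles (0-100) for the internal knots.
#' @return A `basis_spec`.
#' @export
default_exposure_spec <- function(tapp, knot_percentiles = c(25, 75)) {
  x <- if (is.data.frame(tapp)) tapp$tapp_c else tapp
  x <- x[!is.na(x)]
  basis_spec("ns",
             internal_knots = stats::quantile(x, knot_percentiles / 100,
                                              names = FALSE),
             boundary_knots = range(x), intercept = FALSE)
}

#' Default lag basis
#' @param max_lag Maximum lag in days.
#' @param n_knots Internal knots on the log-lag scale.
#' @return A `basis_spec` with an intercept.
#' @export
default_lag_spec <- function(max_lag = 21L, n_knots = 3L) {
  basis_spec("ns", internal_knots = default_lag_knots(max_lag, n_knots),
             boundary_knots = c(0, max_lag), intercept = TRUE)
}

#' Build the exposure-lag crossbasis
#'
#' Constructs, from the whole exposure series, the tensor-product design
#' matrix whose row for day \eqn{t} is
#' \deqn{\sum_{l=0}^{L} B_x(x_{t-l}) \otimes B_l(l),}
#' with \eqn{B_x} the exposure basis and \eqn{B_l} the lag basis. Rows are
#' produced for the requested `event_days` (case and referent days alike
#' are looked up in the same whole-series lag matrix), or for every day
#' with a complete lag history when `event_days` is `NULL`.
#'
#' @param tapp A `tapp_series` covering the study span.
#' @param event_days Optional vector of `Date`s to extract rows for. Days
#'   with incomplete or missing exposure history are dropped with a
#'   warning.
#' @param exposure_spec,lag_spec [basis_spec()]s; defaults follow
#'   [default_exposure_spec()] and [default_lag_spec()].
#' @param max_lag Lag window length L in days (lag 0 = the event day).
#' @return A `crossbasis`: the design matrix with attributes `dates` (row
#'   dates), `exposure_spec`, `lag_spec`, `max_lag`, `series` (the
#'   exposure series used) and `dropped` (event days without usable rows).
#' @export
build_crossbasis <- function(tapp, event_days = NULL,
                             exposure_spec = NULL, lag_spec = NULL,
                             max_lag = 21L) {
  stopifnot(is.data.frame(tapp), max_lag >= 1)
  if (is.null(exposure_spec)) exposure_spec <- default_exposure_spec(tapp)
  if (is.null(lag_spec)) lag_spec <- default_lag_spec(max_lag)
  x <- tapp$tapp_c
  n <- length(x)
  if (n <= max_lag) stop("series shorter than the lag window")
  ok <- !is.na(x)
  vx <- ncol(ns_basis(exposure_spec$boundary_knots, exposure_spec))
  bx <- matrix(NA_real_, n, vx)
  if (any(ok)) bx[ok, ] <- ns_basis(x[ok], exposure_spec)
  bl <- ns_basis(0:max_lag, lag_spec)                   # (L+1) x vl
  vl <- ncol(bl)
  q <- matrix(0, n, vx * vl)
  jx <- rep(seq_len(vx), each = vl)
  jl <- rep(seq_len(vl), times = vx)
  for (l in 0:max_lag) {
    shifted <- rbind(matrix(NA_real_, l, vx),
                     bx[seq_len(n - l), , drop = FALSE])
    q <- q + shifted[, jx, drop = FALSE] *
      matrix(bl[l + 1L, jl], n, vx * vl, byrow = TRUE)
  }
  q[seq_len(min(max_lag, n)), ] <- NA_real_             # incomplete history
  colnames(q) <- paste0("x", jx, ".l", jl)

  usable <- !is.na(q[, 1L])
  if (is.null(event_days)) {
    rows <- which(usable)
    dropped <- as.Date(character())
  } else {
    event_days <- as.Date(event_days)
    rows <- match(event_days, tapp$date)
    miss <- is.na(rows) | !usable[pmax(rows, 1L, na.rm = TRUE)]
    miss[is.na(rows)] <- TRUE
    dropped <- event_days[miss]
    if (length(dropped))
      warning(length(dropped), " event day(s) dropped: incomplete exposure history")
    rows <- rows[!miss]
  }
  structure(q[rows, , drop = FALSE],
            dates = tapp$date[rows],
            exposure_spec = exposure_spec, lag_spec = lag_spec,
            max_lag = as.integer(max_lag), vx = vx, vl = vl,
            series = tapp, dropped = dropped,
            class = c("crossbasis", "matrix"))
}

# exposure-basis difference from the centering value, for a grid
centered_exposure_basis <- function(cb, grid, center) {
  es <- attr(cb, "exposure_spec")
  bk <- es$boundary_knots
  if (center < bk[1L] || center > bk[2L])
    stop("center ", center, " outside the exposure boundary knots [",
         bk[1L], ", ", bk[2L], "]")
  bx <- ns_basis(grid, es)
  bc <- ns_basis(center, es)
  sweep(bx, 2L, bc, "-")
}

# expand an exposure-basis row and a lag-basis row into crossbasis column
# ordering: column (j-1)*vl + k holds bx_j * bl_k (lag index varies fastest)
tensor_row <- function(bx_row, bl_row) {
  rep(bx_row, each = length(bl_row)) * rep(bl_row, times = length(bx_row))
}

#' Cumulative exposure-response prediction
#'
#' Evaluates the lag-cumulated log relative risk (and its variance) over a
#' grid of exposures, centred so the curve is exactly zero at `center`.
#' The cumulative crossbasis vector at exposure x is
#' `(Bx(x) - Bx(center)) %o% colSums(Bl over l = 0..L)`.
#'
#' @param fit A `cc_fit` (or any list with `beta` and `vcov`).
#' @param cb The `crossbasis` the fit used.
#' @param grid Exposure values to evaluate.
#' @param center Centering exposure (inside the boundary knots).
#' @return A data frame `exposure, logrr, var`.
#' @export
predict_cumulative <- function(fit, cb, grid, center) {
  bl <- ns_basis(0:attr(cb, "max_lag"), attr(cb, "lag_spec"))
  bls <- colSums(bl)
  dbx <- centered_exposure_basis(cb, grid, center)
  m <- t(apply(dbx, 1L, tensor_row, bl_row = bls))
  if (ncol(m) != length(fit$beta)) stop("fit dimension does not match crossbasis")
  v <- symmetrize_psd(fit$vcov)
  data.frame(exposure = grid,
             logrr = as.numeric(m %*% fit$beta),
             var = rowSums((m %*% v) * m))
}

#' Lag-response prediction at one exposure
#'
#' Per-lag log relative risk at exposure `at_exposure` relative to
#' `center`, for lags 0..L. Summing `logrr` over lags reproduces the
#' cumulative prediction at the same exposure.
#'
#' @inheritParams predict_cumulative
#' @param at_exposure Exposure value at which to slice the surface.
#' @return A data frame `lag, logrr, var`.
#' @export
predict_lag <- function(fit, cb, at_exposure, center) {
  max_lag <- attr(cb, "max_lag")
  bl <- ns_basis(0:max_lag, attr(cb, "lag_spec"))
  dbx <- centered_exposure_basis(cb, at_exposure, center)[1L, ]
  m <- t(vapply(seq_len(max_lag + 1L),
                function(i) tensor_row(dbx, bl[i, ]),
                numeric(length(dbx) * ncol(bl))))
  if (ncol(m) != length(fit$beta)) stop("fit dimension does not match crossbasis")
  v <- symmetrize_psd(fit$vcov)
  data.frame(lag = 0:max_lag,
             logrr = as.numeric(m %*% fit$beta),
             var = rowSums((m %*% v) * m))
}

# Symmetrize a covariance matrix; tolerate tiny numerical asymmetry.
symmetrize_psd <- function(v) (v + t(v)) / 2
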