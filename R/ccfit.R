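#' Time-stratified referent sets
#'
#' For each fatal-admission case, the referent (control) days are every
#' other day in the same calendar month and year falling on the same day
#' of the week — the time-stratified, bi-directional scheme that makes the
#' case self-matched on weekday, season and long-term trend. Every
#' Gregorian month yields 3 or 4 referents per case. Multiple cases on the
#' same day form distinct strata.
#'
#' @param cases A data frame of case records with at least an
#'   `admission_date` column of class `Date` (see [simulate_cases()] /
#'   [read_cases_csv()]).
#' @return A `cc_strata` data frame in long form with columns `stratum`
#'   (integer id, one per case), `date`, and `case` (logical; exactly one
#'   `TRUE` per stratum).
#' @export
make_strata <- function(cases) {
  d <- as.Date(cases$admission_date)
  if (any(is.na(d))) stop("make_strata: missing admission dates")
  n <- length(d)
  # candidate referents: +/- 5 weeks, trimmed to the case's month
  offs <- 7L * (-5L:5L)
  cand <- rep(d, each = length(offs)) + offs
  strat <- rep(seq_len(n), each = length(offs))
  keep <- format(cand, "%Y-%m") == format(rep(d, each = length(offs)), "%Y-%m")
  out <- data.frame(stratum = strat[keep], date = cand[keep],
                    case = (cand == rep(d, each = length(offs)))[keep])
  out <- out[order(out$stratum, out$date), ]
  rownames(out) <- NULL
  class(out) <- c("cc_strata", "data.frame")
  out
}

#' Dump strata for audit
#' @param strata A `cc_strata`.
#' @param path CSV path; written columns are `case_id,case_day,control_day`.
#' @return Invisibly, `path`.
#' @export
write_strata_csv <- function(strata, path) {
  case_day <- strata$date[strata$case][strata$stratum]
  ctl <- strata[!strata$case, ]
  df <- data.frame(case_id = ctl$stratum,
                   case_day = format(case_day[ctl$stratum]),
                   control_day = format(ctl$date))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# columns with essentially no within-stratum variation are unidentifiable
# under the conditional likelihood
find_aliased <- function(x, strat) {
  resid <- apply(x, 2L, function(col) col - stats::ave(col, strat))
  scale <- pmax(apply(abs(x), 2L, max), 1)
  apply(abs(resid), 2L, max) < 1e-10 * scale
}

# p: within-stratum softmax probabilities aligned row-wise; the conditional
# log-likelihood uses that each stratum holds exactly one case row
cond_loglik_parts <- function(x, beta, strat, case_rows) {
  eta <- as.numeric(x %*% beta)
  mx <- stats::ave(eta, strat, FUN = max)
  w <- exp(eta - mx)
  denom <- stats::ave(w, strat, FUN = sum)
  p <- w / denom
  ll <- sum(eta[case_rows] - mx[case_rows] - log(denom[case_rows]))
  list(ll = ll, p = p)
}

#' Fit the conditional (case-crossover) likelihood
#'
#' Maximises the conditional logistic log-likelihood
#' \deqn{\ell(\beta) = \sum_s \Big[ x_{case(s)}\beta -
#'   \log \sum_{d \in s} e^{x_d \beta} \Big]}
#' over the crossbasis coefficients by damped Newton iterations (step
#' halving; convergence on the gradient max-norm). The "binomial
#' likelihood" of a 1:M matched case-crossover is exactly this matched-set
#' conditional likelihood. The covariance is the inverse observed
#' information at the optimum. Crossbasis columns without within-stratum
#' variation are unidentifiable and are excluded (reported via `aliased`,
#' with zero coefficient and variance).
#'
#' @param strata A `cc_strata` from [make_strata()].
#' @param cb A `crossbasis` built over the whole series
#'   (`event_days = NULL`); stratum days are looked up in it by date.
#'   Strata containing any day without a usable crossbasis row (missing
#'   exposure or incomplete lag history) are dropped with a warning.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return A `cc_fit`: list with `beta`, `vcov` (full crossbasis
#'   dimension), `loglik`, `n_strata`, `n_parameters` (identifiable),
#'   `converged`, `iterations`, `aliased`, `n_dropped_strata`.
#' @export
fit_conditional <- function(strata, cb, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(strata, "cc_strata"))
  rows <- match(strata$date, attr(cb, "dates"))
  bad_strata <- unique(strata$stratum[is.na(rows)])
  if (length(bad_strata))
    warning(length(bad_strata),
            " stratum/strata dropped: day(s) without crossbasis row")
  keep <- !(strata$stratum %in% bad_strata)
  strat <- match(strata$stratum[keep], unique(strata$stratum[keep]))
  x <- unclass(cb)[rows[keep], , drop = FALSE]
  case_rows <- which(strata$case[keep])
  n_strata <- length(unique(strat))
  if (n_strata < 1L) stop("fit_conditional: no usable strata")
  p_full <- ncol(x)

  aliased <- find_aliased(x, strat)
  beta_full <- stats::setNames(numeric(p_full), colnames(x))
  vcov_full <- matrix(0, p_full, p_full,
                      dimnames = list(colnames(x), colnames(x)))
  if (all(aliased)) {
    ll <- -sum(log(table(strat)))
    return(structure(list(beta = beta_full, vcov = vcov_full, loglik = ll,
                          n_strata = n_strata, n_parameters = 0L,
                          converged = TRUE, iterations = 0L,
                          aliased = aliased,
                          n_dropped_strata = length(bad_strata)),
                     class = "cc_fit"))
  }
  xr <- x[, !aliased, drop = FALSE]
  p <- ncol(xr)
  beta <- numeric(p)
  parts <- cond_loglik_parts(xr, beta, strat, case_rows)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- parts$p
    grad <- colSums(xr[case_rows, , drop = FALSE]) -
      as.numeric(crossprod(xr, w))
    if (max(abs(grad)) < tol) { converged <- TRUE; iter <- iter - 1L; break }
    mu <- rowsum(xr * w, strat)
    info <- crossprod(xr * sqrt(w)) - crossprod(mu)
    step <- tryCatch(solve(info, grad),
                     error = function(e) stop("fit_conditional: singular ",
                                              "information matrix"))
    # damping: halve until the likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      new_parts <- cond_loglik_parts(xr, cand, strat, case_rows)
      if (new_parts$ll >= parts$ll - 1e-12 || lam < 2^-30) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    parts <- new_parts
    if (sqrt(sum(beta^2)) > 50)
      stop("fit_conditional: diverging coefficients (complete separation?)")
  }
  if (!converged) {
    w <- parts$p
    grad <- colSums(xr[case_rows, , drop = FALSE]) -
      as.numeric(crossprod(xr, w))
    converged <- max(abs(grad)) < tol
  }
  w <- parts$p
  mu <- rowsum(xr * w, strat)
  info <- crossprod(xr * sqrt(w)) - crossprod(mu)
  vr <- solve(info)
  beta_full[!aliased] <- beta
  vcov_full[!aliased, !aliased] <- (vr + t(vr)) / 2
  structure(list(beta = beta_full, vcov = vcov_full, loglik = parts$ll,
                 n_strata = n_strata, n_parameters = p,
                 converged = converged, iterations = iter,
                 aliased = aliased,
                 n_dropped_strata = length(bad_strata)),
            class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("Conditional case-crossover fit:", x$n_parameters, "parameter(s),",
      x$n_strata, "strata\n")
  cat("log-likelihood:", format(x$loglik), " converged:", x$converged,
      "(", x$iterations, "iterations )\n")
  invisible(x)
}

#' Quasi-Poisson time-series fit (sensitivity alternative)
#'
#' Log-linear model of daily death counts on the crossbasis plus a natural
#' cubic spline of calendar time (seasonality and trend) and day-of-week
#' indicators, with variance inflated by the Pearson overdispersion
#' estimate.
#'
#' @param daily_deaths Data frame with columns `date` and `deaths`
#'   (non-negative integer counts).
#' @param cb A `crossbasis` built with `event_days = NULL`; only days
#'   present in both inputs are modelled.
#' @param df_per_year Degrees of freedom per year for the calendar-time
#'   spline (default 7).
#' @param dow Include day-of-week indicators (default TRUE).
#' @return A `cc_fit`-compatible list restricted to the crossbasis terms,
#'   with an extra `dispersion` element.
#' @export
fit_quasipoisson <- function(daily_deaths, cb, df_per_year = 7, dow = TRUE) {
  idx <- match(attr(cb, "dates"), as.Date(daily_deaths$date))
  keep <- !is.na(idx)
  y <- daily_deaths$deaths[idx[keep]]
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  if (all(y == 0)) stop("fit_quasipoisson: all counts are zero")
  x <- unclass(cb)[keep, , drop = FALSE]
  dates <- attr(cb, "dates")[keep]
  t_num <- as.numeric(dates)
  years <- (max(t_num) - min(t_num) + 1) / 365.25
  df_time <- max(3L, round(df_per_year * years))
  tm <- splines::ns(t_num, df = df_time)
  dat <- data.frame(y = y)
  form <- y ~ cbx + tm
  dat$cbx <- x
  dat$tm <- tm
  if (dow) {
    dat$dw <- factor(weekdays(dates))
    form <- y ~ cbx + tm + dw
  }
  gf <- stats::glm(form, family = stats::quasipoisson(), data = dat)
  co <- stats::coef(gf)
  vc <- stats::vcov(gf)
  cb_names <- paste0("cbx", colnames(cb))
  beta <- stats::setNames(numeric(ncol(cb)), colnames(cb))
  vcov_full <- matrix(0, ncol(cb), ncol(cb),
                      dimnames = list(colnames(cb), colnames(cb)))
  hit <- match(cb_names, names(co))
  est <- co[hit]
  est[is.na(est)] <- 0
  beta[] <- est
  ok <- !is.na(hit) & cb_names %in% rownames(vc)
  vcov_full[ok, ok] <- vc[cb_names[ok], cb_names[ok]]
  structure(list(beta = beta, vcov = vcov_full, loglik = NA_real_,
                 n_strata = length(y), n_parameters = sum(!is.na(co)),
                 converged = gf$converged, iterations = gf$iter,
                 aliased = is.na(co[cb_names]),
                 dispersion = summary(gf)$dispersion),
            class = "cc_fit")
}
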