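test_that("referents are every other same-weekday day in the month", {
  st <- make_strata(data.frame(admission_date = as.Date("2016-03-15")))
  expect_equal(st$date[!st$case],
               as.Date(c("2016-03-01", "2016-03-08", "2016-03-22",
                         "2016-03-29")))
  expect_equal(st$date[st$case], as.Date("2016-03-15"))

  # a weekday occurring 4 times that month leaves exactly 3 referents
  st4 <- make_strata(data.frame(admission_date = as.Date("2016-03-04")))
  expect_equal(sum(!st4$case), 3L)
})

test_that("referent properties hold over random dates", {
  set.seed(21)
  d <- sample(seq(as.Date("2011-01-01"), as.Date("2020-12-31"), by = "day"),
              300)
  st <- make_strata(data.frame(admission_date = d))
  for (s in unique(st$stratum)) {
    blk <- st[st$stratum == s, ]
    cd <- blk$date[blk$case]
    expect_length(cd, 1L)
    expect_true(all(format(blk$date, "%u") == format(cd, "%u")))
    expect_true(all(format(blk$date, "%Y-%m") == format(cd, "%Y-%m")))
    expect_false(cd %in% blk$date[!blk$case])
    expect_true(sum(!blk$case) %in% 3:4)
  }
  # same-day cases form distinct strata
  st2 <- make_strata(data.frame(admission_date = rep(d[1], 2)))
  expect_equal(length(unique(st2$stratum)), 2L)
})

test_that("uninformative strata give zero coefficients and the null loglik", {
  # constant series: every stratum day shares one crossbasis row
  tapp <- toy_series(rep(30, 120))
  cb <- build_crossbasis(tapp, exposure_spec = basis_spec("ns", 30.5, c(29, 32)),
                         lag_spec = basis_spec("ns", 1, c(0, 2), intercept = TRUE),
                         max_lag = 2)
  cases <- data.frame(admission_date = tapp$date[c(40, 47, 75)])
  st <- make_strata(cases)
  fit <- fit_conditional(st, cb)
  expect_equal(unname(fit$beta), rep(0, ncol(cb)))
  expect_true(all(fit$aliased))
  sizes <- table(st$stratum)
  expect_equal(fit$loglik, -sum(log(sizes)))
  expect_true(fit$converged)
})

# hand-built one-column strata: the conditional likelihood can be written
# out and maximized by golden-section search as an independent oracle
test_that("Newton matches scalar maximization on one-parameter strata", {
  set.seed(31)
  n_strata <- 25L
  sizes <- sample(3:4, n_strata, replace = TRUE)
  xs <- lapply(seq_len(n_strata), function(i) rnorm(sizes[i] + 1L))
  truth_beta <- 0.8
  case_pick <- vapply(xs, function(x) {
    p <- exp(truth_beta * x); sample(length(x), 1L, prob = p / sum(p))
  }, integer(1L))

  ll <- function(b) sum(vapply(seq_len(n_strata), function(i) {
    eta <- b * xs[[i]]
    eta[case_pick[i]] - log(sum(exp(eta)))
  }, numeric(1L)))
  oracle <- optimize(ll, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum

  # pack the same data through the package's fitter via a fake crossbasis
  rows <- do.call(c, xs)
  dates <- as.Date("2015-01-01") + seq_along(rows) - 1L
  cb <- structure(matrix(rows, ncol = 1, dimnames = list(NULL, "x1.l1")),
                  dates = dates, class = c("crossbasis", "matrix"))
  long <- data.frame(
    stratum = rep(seq_len(n_strata), times = sizes + 1L),
    date = dates,
    case = unlist(lapply(seq_len(n_strata), function(i)
      seq_len(sizes[i] + 1L) == case_pick[i])))
  class(long) <- c("cc_strata", "data.frame")
  fit <- fit_conditional(long, cb)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-6)
  expect_equal(fit$loglik, ll(oracle), tolerance = 1e-8)
})

make_toy_problem <- function(p, n_strata, seed) {
  set.seed(seed)
  sizes <- sample(3:4, n_strata, replace = TRUE) + 1L
  x <- matrix(rnorm(sum(sizes) * p), ncol = p)
  strat <- rep(seq_len(n_strata), times = sizes)
  beta_true <- rnorm(p, sd = 0.5)
  case <- logical(nrow(x))
  for (s in seq_len(n_strata)) {
    idx <- which(strat == s)
    pr <- exp(x[idx, , drop = FALSE] %*% beta_true)
    case[sample(idx, 1L, prob = pr / sum(pr))] <- TRUE
  }
  list(x = x, strat = strat, case = case, sizes = sizes)
}

toy_to_objects <- function(tp) {
  dates <- as.Date("2015-01-01") + seq_len(nrow(tp$x)) - 1L
  cb <- structure(tp$x, dates = dates,
                  class = c("crossbasis", "matrix"))
  colnames(cb) <- paste0("c", seq_len(ncol(tp$x)))
  long <- data.frame(stratum = tp$strat, date = dates, case = tp$case)
  class(long) <- c("cc_strata", "data.frame")
  list(cb = cb, strata = long)
}

toy_loglik <- function(tp) function(b) {
  eta <- as.numeric(tp$x %*% b)
  sum(vapply(unique(tp$strat), function(s) {
    idx <- tp$strat == s
    eta[idx & tp$case] - log(sum(exp(eta[idx])))
  }, numeric(1L)))
}

test_that("Newton matches a generic optimizer on five-parameter instances", {
  for (seed in c(101, 202)) {
    tp <- make_toy_problem(5L, 60L, seed)
    ob <- toy_to_objects(tp)
    fit <- fit_conditional(ob$strata, ob$cb)
    ll <- toy_loglik(tp)
    generic <- optim(rep(0, 5), function(b) -ll(b), method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14))
    expect_true(fit$converged)
    expect_equal(unname(fit$beta), generic$par, tolerance = 1e-5)
    expect_gte(fit$loglik, -generic$value - 1e-8)
  }
})

test_that("the fitter agrees with conditional logistic regression", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  tp <- make_toy_problem(4L, 80L, 303)
  ob <- toy_to_objects(tp)
  fit <- fit_conditional(ob$strata, ob$cb)
  cl <- survival::clogit(case ~ x + strata(strat),
                         data = data.frame(case = tp$case, x = I(tp$x),
                                           strat = tp$strat))
  expect_equal(unname(fit$beta), unname(coef(cl)), tolerance = 1e-5)
  expect_equal(unname(fit$vcov), unname(vcov(cl)), tolerance = 1e-4)
})

test_that("duplicating every stratum keeps beta and halves the covariance", {
  tp <- make_toy_problem(3L, 50L, 404)
  ob <- toy_to_objects(tp)
  fit1 <- fit_conditional(ob$strata, ob$cb)
  tp2 <- list(x = rbind(tp$x, tp$x),
              strat = c(tp$strat, tp$strat + max(tp$strat)),
              case = c(tp$case, tp$case))
  ob2 <- toy_to_objects(tp2)
  fit2 <- fit_conditional(ob2$strata, ob2$cb)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-6)
  expect_equal(fit2$vcov, fit1$vcov / 2, tolerance = 1e-5)
})

test_that("stratum-constant columns are flagged unidentifiable", {
  tp <- make_toy_problem(2L, 40L, 505)
  # add a column constant within every stratum (a day-invariant covariate)
  const_col <- ave(rnorm(length(tp$strat)), tp$strat)
  tp$x <- cbind(tp$x, const_col)
  ob <- toy_to_objects(tp)
  fit <- fit_conditional(ob$strata, ob$cb)
  expect_true(fit$aliased[3L])
  expect_false(any(fit$aliased[1:2]))
  expect_equal(unname(fit$beta[3L]), 0)
  expect_equal(fit$n_parameters, 2L)
})

test_that("strata touching unusable days are dropped with a warning", {
  ts <- small_study()
  tapp_gap <- ts$tapp
  tapp_gap$tapp_c[200:210] <- NA                 # a long weather outage
  cb <- build_crossbasis(tapp_gap)
  expect_warning(fit <- fit_conditional(ts$strata, cb), "dropped")
  expect_gt(fit$n_dropped_strata, 0)
  expect_true(fit$converged)
})

test_that("quasi-Poisson dispersion is near 1 under a correct Poisson model", {
  ts <- small_study()
  set.seed(61)
  # regenerate counts from a Poisson law with a known smooth signal
  cb <- ts$cb
  dates <- attr(cb, "dates")
  eta <- 0.1 + as.numeric(unclass(cb) %*% rnorm(ncol(cb), sd = 0.005))
  y <- rpois(length(eta), exp(eta))
  dd <- data.frame(date = dates, deaths = y)
  fit <- fit_quasipoisson(dd, cb)
  expect_true(fit$converged)
  expect_lt(abs(fit$dispersion - 1), 0.1)
  expect_error(fit_quasipoisson(data.frame(date = dates, deaths = 0 * y), cb),
               "all counts are zero")
})

test_that("conditional and quasi-Poisson cumulative curves agree", {
  ts <- small_study()
  qp <- fit_quasipoisson(ts$deaths, ts$cb)
  ctr <- ts$mmt$mmt
  grid <- seq(ts$mmt$search_range[1], ts$mmt$search_range[2], by = 0.5)
  cc <- cumulative_curve(ts$fit, ts$cb, ctr, grid = grid)
  qc <- cumulative_curve(qp, ts$cb, ctr, grid = grid)
  # cross-method consistency: each curve inside the union of the two CIs
  inside <- qc$rr <= pmax(cc$rr_high, qc$rr_high) + 1e-9 &
    qc$rr >= pmin(cc$rr_low, qc$rr_low) - 1e-9
  expect_true(mean(inside) > 0.95)
})
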