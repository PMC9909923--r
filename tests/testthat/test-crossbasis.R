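test_that("basis_spec validates knot geometry", {
  expect_error(basis_spec("ns", c(3, 2), c(0, 10)), "strictly increasing")
  expect_error(basis_spec("ns", c(0, 5), c(0, 10)), "strictly inside")
  expect_error(basis_spec("ns", 5, c(10, 0)), "increasing pair")
  sp <- basis_spec("ns", c(2, 5), c(0, 10))
  expect_s3_class(sp, "basis_spec")
})

test_that("the natural spline space contains linear functions", {
  sp <- basis_spec("ns", c(28, 34), c(22, 42))
  x <- seq(20, 44, by = 0.25)            # includes extrapolation region
  b <- cbind(1, ns_basis(x, sp))         # affine span
  target <- 3 - 0.7 * x
  co <- qr.solve(b, target)
  expect_lt(max(abs(b %*% co - target)), 1e-9)
})

test_that("basis columns are linear beyond the boundary knots", {
  sp <- basis_spec("ns", c(28, 34), c(22, 42))
  for (x0 in c(10, 45)) {                # both tails
    x <- x0 + c(0, 1, 2)
    b <- ns_basis(x, sp)
    second_diff <- b[1, ] - 2 * b[2, ] + b[3, ]
    expect_lt(max(abs(second_diff)), 1e-10)
  }
})

test_that("least squares recovers a natural-spline target exactly", {
  # oracle: stats::splinefun(method = "natural") interpolates with a
  # natural cubic spline on the same knot set, so it lies in the span
  knots <- c(22, 28, 34, 42)
  f <- splinefun(knots, c(0.4, -0.2, 0.5, 0.1), method = "natural")
  sp <- basis_spec("ns", knots[2:3], knots[c(1, 4)])
  x <- seq(22, 42, by = 0.1)
  b <- cbind(1, ns_basis(x, sp))
  co <- qr.solve(b, f(x))
  expect_lt(max(abs(b %*% co - f(x))), 1e-8)
})

test_that("lag knots are log-equally spaced", {
  expect_equal(default_lag_knots(21, 3), 21^(c(1, 2, 3) / 4),
               tolerance = 1e-12)
  expect_equal(default_lag_knots(21, 3), c(2.14069514, 4.58257569, 9.80989753),
               tolerance = 1e-7)
  expect_equal(default_lag_knots(16, 1), 4)
  for (L in c(2, 5, 21, 40))
    for (k in 1:4)
      expect_true(is.unsorted(default_lag_knots(L, k)) == FALSE)
})

test_that("constant exposure series gives identical tensor-sum rows", {
  tapp <- toy_series(rep(31, 40))
  es <- basis_spec("ns", c(28, 34), c(22, 42))
  ls <- basis_spec("ns", c(2, 4), c(0, 7), intercept = TRUE)
  cb <- build_crossbasis(tapp, exposure_spec = es, lag_spec = ls, max_lag = 7)
  expect_true(all(apply(cb, 2, function(col) max(col) - min(col)) < 1e-12))
  bx <- ns_basis(31, es)[1, ]
  bls <- colSums(ns_basis(0:7, ls))
  expected <- unname(rep(bx, each = length(bls)) * rep(bls, times = length(bx)))
  expect_equal(unname(cb[1, ]), expected, tolerance = 1e-12)
})

test_that("crossbasis rows equal a brute-force triple loop", {
  set.seed(7)
  x <- runif(30, 24, 40)
  tapp <- toy_series(x)
  es <- basis_spec("ns", c(30), c(24, 40))
  ls <- basis_spec("ns", c(1), c(0, 2), intercept = TRUE)
  cb <- build_crossbasis(tapp, event_days = tapp$date[c(10, 20)],
                         exposure_spec = es, lag_spec = ls, max_lag = 2)
  for (r in 1:2) {
    t_idx <- c(10, 20)[r]
    vx <- 2; vl <- 3
    row <- numeric(vx * vl)
    for (l in 0:2) {
      bx <- ns_basis(x[t_idx - l], es)[1, ]
      bl <- ns_basis(l, ls)[1, ]
      for (j in 1:vx) for (k in 1:vl)
        row[(j - 1) * vl + k] <- row[(j - 1) * vl + k] + bx[j] * bl[k]
    }
    expect_equal(unname(cb[r, ]), row, tolerance = 1e-12)
  }
})

test_that("a row depends only on the exposures inside its lag window", {
  set.seed(8)
  x <- runif(80, 24, 40)
  es <- basis_spec("ns", c(30), c(20, 44))
  ls <- basis_spec("ns", c(2), c(0, 5), intercept = TRUE)
  day <- 50L
  base_row <- function(xv) {
    cb <- build_crossbasis(toy_series(xv), event_days = toy_series(xv)$date[day],
                           exposure_spec = es, lag_spec = ls, max_lag = 5)
    unname(cb[1, ])
  }
  r0 <- base_row(x)
  x_out <- x; x_out[c(10, 44, 56, 80)] <- x_out[c(10, 44, 56, 80)] + 3
  expect_equal(base_row(x_out), r0, tolerance = 1e-14)
  x_in <- x; x_in[day - 3L] <- x_in[day - 3L] + 1
  expect_false(isTRUE(all.equal(base_row(x_in), r0)))
})

test_that("event-day ordering permutes rows identically", {
  set.seed(9)
  x <- runif(60, 24, 40)
  tapp <- toy_series(x)
  days <- tapp$date[c(30, 40, 55, 35)]
  cb1 <- build_crossbasis(tapp, event_days = days, max_lag = 21)
  cb2 <- build_crossbasis(tapp, event_days = rev(days), max_lag = 21)
  expect_equal(unclass(cb1)[4:1, ], unclass(cb2)[1:4, ],
               ignore_attr = TRUE)
})

test_that("event days without full history are dropped with a warning", {
  tapp <- toy_series(runif(50, 24, 40))
  expect_warning(
    cb <- build_crossbasis(tapp, event_days = tapp$date[c(3, 40)],
                           max_lag = 21),
    "incomplete")
  expect_equal(nrow(cb), 1L)
  expect_equal(attr(cb, "dropped"), tapp$date[3])
})

test_that("cumulative prediction obeys the centering identity and null fit", {
  tf <- tiny_fit()
  ctr <- 31
  pr <- predict_cumulative(tf$fit, tf$cb, c(27, ctr, 35), center = ctr)
  expect_identical(pr$logrr[2], 0)
  expect_identical(pr$var[2], 0)
  null_fit <- list(beta = numeric(length(tf$fit$beta)),
                   vcov = matrix(0, length(tf$fit$beta), length(tf$fit$beta)),
                   converged = TRUE)
  pr0 <- predict_cumulative(null_fit, tf$cb, seq(26, 36), center = 31)
  expect_equal(pr0$logrr, rep(0, 11))
  expect_error(predict_cumulative(tf$fit, tf$cb, 30, center = 100), "outside")
})

test_that("cumulative and lag predictions match the per-lag loop oracle", {
  tf <- tiny_fit()
  beta <- tf$fit$beta
  ctr <- 30.5
  grid <- c(26.5, 29, 33.8)
  bl <- ns_basis(0:5, tf$ls)
  vl <- ncol(bl)
  brute_cum <- sapply(grid, function(g) {
    dbx <- ns_basis(g, tf$es)[1, ] - ns_basis(ctr, tf$es)[1, ]
    tot <- 0
    for (l in 0:5) {
      row <- rep(dbx, each = vl) * rep(bl[l + 1, ], times = length(dbx))
      tot <- tot + sum(row * beta)
    }
    tot
  })
  pr <- predict_cumulative(tf$fit, tf$cb, grid, center = ctr)
  expect_equal(pr$logrr, brute_cum, tolerance = 1e-10)

  pl <- predict_lag(tf$fit, tf$cb, at_exposure = 33.8, center = ctr)
  expect_equal(sum(pl$logrr), pr$logrr[3], tolerance = 1e-10)
  dbx3 <- ns_basis(33.8, tf$es)[1, ] - ns_basis(ctr, tf$es)[1, ]
  expect_equal(pl$logrr[3],
               sum((rep(dbx3, each = vl) * rep(bl[3, ], length(dbx3))) * beta),
               tolerance = 1e-10)
  pl0 <- predict_lag(tf$fit, tf$cb, at_exposure = ctr, center = ctr)
  expect_equal(pl0$logrr, rep(0, 6))
})

test_that("fitted curves are invariant to invertible recombination of columns", {
  tf <- tiny_fit()
  cb <- tf$cb
  p <- ncol(cb)
  set.seed(77)
  tr <- diag(p) + matrix(rnorm(p * p, sd = 0.15), p, p)
  cb2 <- cb
  cb2[, ] <- unclass(cb) %*% tr
  cases <- data.frame(admission_date = attr(cb, "dates")[
    seq(10, nrow(cb), by = 3)])
  strata <- make_strata(cases)
  f1 <- suppressWarnings(fit_conditional(strata, cb))
  f2 <- suppressWarnings(fit_conditional(strata, cb2))
  grid <- seq(27, 35, by = 0.5)
  ctr <- 31
  m <- t(sapply(grid, function(g) {
    dbx <- ns_basis(g, tf$es)[1, ] - ns_basis(ctr, tf$es)[1, ]
    bls <- colSums(ns_basis(0:5, tf$ls))
    rep(dbx, each = length(bls)) * rep(bls, times = length(dbx))
  }))
  c1 <- as.numeric(m %*% f1$beta)
  c2 <- as.numeric((m %*% tr) %*% f2$beta)
  expect_equal(c1, c2, tolerance = 1e-6)
})
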