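# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# hand-built exposure series wrapped as a tapp_series
toy_series <- function(values, start = as.Date("2015-01-01")) {
  structure(data.frame(date = start + seq_along(values) - 1L,
                       tapp_c = values,
                       n_stations = 2L),
            class = c("tapp_series", "data.frame"))
}

# three synthetic study years, fitted end to end; used by effects /
# attribution / acceptance convention tests
small_study <- function() {
  cached("small_study", function() {
    cl <- climate_spec(start_date = "2014-01-01", end_date = "2016-12-31",
                       seed = 11L)
    tapp <- build_regional_series(simulate_weather(cl))
    surface <- surface_spec()
    cases <- simulate_cases(tapp, surface, baseline_rate = 1.1, seed = 12L)
    cb <- build_crossbasis(tapp)
    strata <- make_strata(cases)
    fit <- suppressWarnings(fit_conditional(strata, cb))
    deaths <- daily_death_counts(cases, dates = tapp$date)
    mmt <- find_mmt(fit, cb)
    list(climate = cl, tapp = tapp, surface = surface, cases = cases,
         cb = cb, strata = strata, fit = fit, deaths = deaths, mmt = mmt)
  })
}

# a small crossbasis + fit on a short hand-seeded series, cheap enough for
# brute-force oracles
tiny_fit <- function() {
  cached("tiny_fit", function() {
    set.seed(301)
    x <- 30 + 4 * sin(seq_len(220) / 9) + rnorm(220)
    tapp <- toy_series(x)
    es <- basis_spec("ns", internal_knots = quantile(x, c(0.25, 0.75)),
                     boundary_knots = range(x))
    ls <- basis_spec("ns", internal_knots = c(1.5, 3), boundary_knots = c(0, 5),
                     intercept = TRUE)
    cb <- build_crossbasis(tapp, exposure_spec = es, lag_spec = ls,
                           max_lag = 5L)
    ncase <- 60L
    case_days <- sample(tapp$date[-(1:30)], ncase)
    cases <- data.frame(admission_date = case_days)
    strata <- make_strata(cases)
    fit <- suppressWarnings(fit_conditional(strata, cb))
    list(tapp = tapp, cb = cb, fit = fit, es = es, ls = ls)
  })
}

# least-squares pseudo-fit whose cumulative curve approximates a target
# function on a grid; used to plant curves with known shape
pseudo_fit <- function(cb, target_fun, grid, center) {
  es <- attr(cb, "exposure_spec")
  ls <- attr(cb, "lag_spec")
  bls <- colSums(ns_basis(0:attr(cb, "max_lag"), ls))
  m <- t(sapply(grid, function(g) {
    dbx <- ns_basis(g, es)[1, ] - ns_basis(center, es)[1, ]
    rep(dbx, each = length(bls)) * rep(bls, times = length(dbx))
  }))
  beta <- qr.solve(qr(m, LAPACK = TRUE), target_fun(grid))
  list(beta = as.numeric(beta), vcov = diag(0, length(beta)),
       converged = TRUE)
}

# a series + crossbasis with a knot-rich exposure basis, so smooth targets
# are representable almost exactly
rich_cb <- function() {
  cached("rich_cb", function() {
    set.seed(71)
    x <- runif(400, 24, 42)
    tapp <- toy_series(x)
    es <- basis_spec("ns", internal_knots = seq(26, 40, by = 2),
                     boundary_knots = c(24, 42))
    build_crossbasis(tapp, exposure_spec = es, max_lag = 21)
  })
}
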