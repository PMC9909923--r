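#' Climate specification for the synthetic weather generator
#'
#' Defaults emulate a tropical coastal climate: dry-bulb temperature with
#' a modest seasonal cycle and AR(1) day-to-day persistence, humidity
#' around 76.6% and light winds, so the derived apparent temperature has
#' mean about 33.5 C and a realistic 23-42 C span over a decade.
#'
#' @param start_date,end_date Study span (inclusive), `Date` or ISO text.
#' @param annual_mean Mean dry-bulb temperature, deg C.
#' @param seasonal_amplitude Amplitude of the annual sinusoid, deg C.
#' @param seasonal_phase Phase of the sinusoid, radians.
#' @param ar1_coefficient Lag-1 autocorrelation of the daily anomaly
#'   (|.| < 1).
#' @param daily_sd Marginal standard deviation of the anomaly, deg C.
#' @param rh_mean,rh_sd Relative humidity mean and sd (%; truncated to
#'   \[0, 100\]).
#' @param ws_mean,ws_sd Wind speed mean and sd (m/s; truncated at 0).
#' @param station_sd Station-level perturbation sd, deg C (two stations
#'   with correlated but unequal readings are emitted).
#' @param seed Integer seed.
#' @return A `climate_spec`.
#' @export
climate_spec <- function(start_date = "2011-01-01", end_date = "2020-12-31",
                         annual_mean = 28.6, seasonal_amplitude = 2.0,
                         seasonal_phase = -2.2, ar1_coefficient = 0.7,
                         daily_sd = 1.5, rh_mean = 76.6, rh_sd = 3.4,
                         ws_mean = 1.4, ws_sd = 0.5, station_sd = 0.3,
                         seed = 1L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date <= start_date) stop("climate_spec: end_date must be after start_date")
  if (abs(ar1_coefficient) >= 1) stop("climate_spec: |ar1_coefficient| must be < 1")
  if (daily_sd < 0 || rh_sd < 0 || ws_sd < 0 || station_sd < 0)
    stop("climate_spec: negative standard deviation")
  structure(list(start_date = start_date, end_date = end_date,
                 annual_mean = annual_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_phase = seasonal_phase,
                 ar1_coefficient = ar1_coefficient, daily_sd = daily_sd,
                 rh_mean = rh_mean, rh_sd = rh_sd,
                 ws_mean = ws_mean, ws_sd = ws_sd,
                 station_sd = station_sd, seed = as.integer(seed)),
            class = "climate_spec")
}

# truncated-normal draws by inverse-CDF; exact and reproducible
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate two-station daily weather records
#'
#' Regional dry-bulb temperature follows a seasonal sinusoid plus
#' stationary AR(1) noise; humidity and wind speed are truncated-normal
#' draws. Two stations are emitted, each the regional value plus small
#' independent perturbations, to exercise the station-averaging path.
#'
#' @param spec A [climate_spec()].
#' @return A data frame of weather records (`date, station_id, ta_c,
#'   rh_pct, ws_ms`) suitable for [build_regional_series()].
#' @export
simulate_weather <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  set.seed(spec$seed)
  dates <- seq(spec$start_date, spec$end_date, by = "day")
  n <- length(dates)
  doy <- as.numeric(dates - spec$start_date)
  seas <- spec$annual_mean +
    spec$seasonal_amplitude * sin(2 * pi * doy / 365.25 + spec$seasonal_phase)
  rho <- spec$ar1_coefficient
  innov_sd <- spec$daily_sd * sqrt(1 - rho^2)
  e <- numeric(n)
  e[1L] <- stats::rnorm(1L, 0, spec$daily_sd)
  if (n > 1L) {
    z <- stats::rnorm(n - 1L, 0, innov_sd)
    for (t in 2:n) e[t] <- rho * e[t - 1L] + z[t - 1L]
  }
  ta <- seas + e
  rh <- rtruncnorm(n, spec$rh_mean, spec$rh_sd, 0, 100)
  ws <- rtruncnorm(n, spec$ws_mean, spec$ws_sd, 0, Inf)
  st <- lapply(c("ST1", "ST2"), function(id) {
    data.frame(date = dates, station_id = id,
               ta_c = ta + stats::rnorm(n, 0, spec$station_sd),
               rh_pct = pmin(100, pmax(0, rh + stats::rnorm(n, 0, spec$station_sd))),
               ws_ms = pmax(0, ws + stats::rnorm(n, 0, spec$station_sd / 3)))
  })
  do.call(rbind, st)
}

#' Exposure-lag-response surface specification
#'
#' Defines the true generating surface for the case simulator: a U-shaped
#' cumulative exposure-response with its minimum at `mmt_true`, split into
#' a cold arm distributed over lags with geometric (almost immediate,
#' decaying) weights and a heat arm with a delayed hump peaking at
#' `heat_onset_lag` days. Each arm is piecewise quadratic near the MMT,
#' blending smoothly to a linear asymptote of the stated slope — a shape
#' deliberately outside the natural-spline family the model fits, so
#' parameter recovery is a fair test.
#'
#' @param mmt_true True minimum-mortality temperature, deg C.
#' @param cold_slope,heat_slope Cumulative log-RR per deg C at the cold /
#'   heat asymptote (non-negative).
#' @param lag_decay Per-day multiplicative decay of the cold-arm lag
#'   weights, in (0, 1).
#' @param heat_onset_lag Lag (days) at which the heat-arm weight peaks.
#' @param max_lag Lag window length, days (default 21).
#' @param blend_width Half-width of the quadratic blend zone, deg C.
#' @return A `surface_spec`.
#' @export
surface_spec <- function(mmt_true = 33, cold_slope = 0.10,
                         heat_slope = 0.07, lag_decay = 0.75,
                         heat_onset_lag = 4, max_lag = 21L,
                         blend_width = 1) {
  if (cold_slope < 0 || heat_slope < 0)
    stop("surface_spec: slopes must be non-negative")
  if (lag_decay <= 0 || lag_decay >= 1)
    stop("surface_spec: lag_decay must be in (0, 1)")
  if (max_lag < 1) stop("surface_spec: max_lag must be >= 1")
  if (heat_onset_lag < 1 || heat_onset_lag > max_lag)
    stop("surface_spec: heat_onset_lag must be in [1, max_lag]")
  structure(list(mmt_true = mmt_true, cold_slope = cold_slope,
                 heat_slope = heat_slope, lag_decay = lag_decay,
                 heat_onset_lag = heat_onset_lag,
                 max_lag = as.integer(max_lag), blend_width = blend_width),
            class = "surface_spec")
}

# quadratic-to-linear blend: 0 for u <= 0, u^2/(2 d) on (0, d], u - d/2 beyond
hinge_blend <- function(u, d) {
  ifelse(u <= 0, 0, ifelse(u <= d, u^2 / (2 * d), u - d / 2))
}

# normalized lag weights for the two arms
surface_lag_weights <- function(spec) {
  l <- 0:spec$max_lag
  wc <- spec$lag_decay^l
  wh <- (l / spec$heat_onset_lag) * exp(1 - l / spec$heat_onset_lag)
  list(cold = wc / sum(wc), heat = wh / sum(wh))
}

#' Evaluate the true surface
#'
#' Per-lag log relative risk \eqn{f(x, l)} of the generating surface.
#'
#' @param spec A [surface_spec()].
#' @param x Exposure value(s), deg C.
#' @param lag Lag(s), whole days in 0..max_lag. `x` and `lag` are
#'   recycled against each other.
#' @return Numeric vector of log relative risks.
#' @export
surface_eval <- function(spec, x, lag) {
  stopifnot(all(lag >= 0), all(lag <= spec$max_lag))
  w <- surface_lag_weights(spec)
  cold <- spec$cold_slope * hinge_blend(spec$mmt_true - x, spec$blend_width)
  heat <- spec$heat_slope * hinge_blend(x - spec$mmt_true, spec$blend_width)
  cold * w$cold[lag + 1L] + heat * w$heat[lag + 1L]
}

# per-day cumulative log-RR (and its cold/heat parts) from the true surface
surface_daily_cumulative <- function(spec, tapp) {
  x <- tapp$tapp_c
  n <- length(x)
  w <- surface_lag_weights(spec)
  coldx <- spec$cold_slope * hinge_blend(spec$mmt_true - x, spec$blend_width)
  heatx <- spec$heat_slope * hinge_blend(x - spec$mmt_true, spec$blend_width)
  coldx[is.na(x)] <- NA; heatx[is.na(x)] <- NA
  cum_cold <- cum_heat <- numeric(n)
  for (l in 0:spec$max_lag) {
    sc <- c(rep(NA_real_, l), coldx[seq_len(n - l)])
    sh <- c(rep(NA_real_, l), heatx[seq_len(n - l)])
    cum_cold <- cum_cold + sc * w$cold[l + 1L]
    cum_heat <- cum_heat + sh * w$heat[l + 1L]
  }
  cum_cold[seq_len(min(spec$max_lag, n))] <- NA
  cum_heat[seq_len(min(spec$max_lag, n))] <- NA
  data.frame(date = tapp$date, cum_cold = cum_cold, cum_heat = cum_heat,
             cum_all = cum_cold + cum_heat)
}

#' True attributable fractions implied by a surface and a series
#'
#' Computes, from the generating surface itself (no fitting), the
#' expected daily death counts and the true backward attributable
#' fractions: per day, \eqn{1 - e^{-\sum_l f(x_{t-l}, l)}} weighted by the
#' expected deaths, with cold and heat parts from the respective arms.
#'
#' @param spec A [surface_spec()].
#' @param tapp A `tapp_series`.
#' @param baseline_rate Expected deaths/day at the MMT.
#' @return List: `af_total`, `af_cold`, `af_heat`, `expected_total`,
#'   `n_days`.
#' @export
true_attributable <- function(spec, tapp, baseline_rate) {
  cum <- surface_daily_cumulative(spec, tapp)
  ok <- !is.na(cum$cum_all)
  lam <- baseline_rate * exp(cum$cum_all[ok])
  tot <- sum(lam)
  list(af_total = sum(lam * (1 - exp(-cum$cum_all[ok]))) / tot,
       af_cold = sum(lam * (1 - exp(-cum$cum_cold[ok]))) / tot,
       af_heat = sum(lam * (1 - exp(-cum$cum_heat[ok]))) / tot,
       expected_total = tot, n_days = sum(ok))
}

#' Simulate individual fatal-admission case records
#'
#' Daily death counts are Poisson with rate
#' \eqn{\lambda_t = \text{baseline} \cdot e^{\sum_l f(x_{t-l}, l)}} driven
#' by the true surface; each count is expanded into individual case
#' records with demographic attributes drawn independently of temperature
#' (sex, age group, CVD classes, comorbidity, length of stay) from
#' configurable proportions that default to a tropical in-hospital CVD
#' case mix (59.7% male, about 59% aged over 60).
#'
#' @param tapp A `tapp_series` covering the study span.
#' @param surface A [surface_spec()].
#' @param baseline_rate Expected deaths/day at the MMT (default 1.1).
#' @param seed Integer seed.
#' @param cap Error if any day's |cumulative log-RR| exceeds this
#'   (default 5), preventing numeric blow-up.
#' @param attr_probs Optional list overriding attribute proportions:
#'   `male`, `age_missing`, age-band weights `age_bands` (named numeric),
#'   `class_probs` (IHD/CVA/OTHER), `extra_class`, `comorbidity`.
#' @return A `case_records` data frame (`admission_date, age, sex,
#'   cvd_classes, comorbidity, days_in_hospital`) with attribute
#'   `daily` (date, lambda, count; only days with full lag history).
#' @export
simulate_cases <- function(tapp, surface, baseline_rate = 1.1, seed = 1L,
                           cap = 5, attr_probs = list()) {
  stopifnot(inherits(surface, "surface_spec"), baseline_rate > 0)
  ap <- utils::modifyList(list(
    male = 0.597, female_missing = 0.001,
    age_bands = c("1-20" = 24, "21-40" = 236, "41-60" = 1371,
                  "61-80" = 1937, "81-104" = 389, missing = 3),
    class_probs = c(IHD = 0.45, CVA = 0.25, OTHER = 0.30),
    extra_class = 0.05, comorbidity = 0.549, stay_geom_p = 0.25), attr_probs)
  cum <- surface_daily_cumulative(surface, tapp)
  ok <- !is.na(cum$cum_all)
  if (!any(ok)) stop("simulate_cases: no day has a complete lag history")
  if (max(abs(cum$cum_all[ok])) > cap)
    stop("simulate_cases: cumulative log-RR exceeds the cap (", cap, ")")
  set.seed(as.integer(seed))
  lam <- baseline_rate * exp(cum$cum_all[ok])
  counts <- stats::rpois(length(lam), lam)
  n <- sum(counts)
  dates <- rep(cum$date[ok], counts)
  bands <- ap$age_bands / sum(ap$age_bands)
  band <- sample(names(bands), n, replace = TRUE, prob = bands)
  age <- vapply(band, function(b) {
    if (b == "missing") return(NA_real_)
    r <- as.numeric(strsplit(b, "-")[[1L]])
    stats::runif(1L, r[1L], r[2L])
  }, numeric(1L))
  sex <- sample(c("M", "F", "unknown"), n, replace = TRUE,
                prob = c(ap$male, 1 - ap$male - ap$female_missing,
                         ap$female_missing))
  cls <- sample(names(ap$class_probs), n, replace = TRUE,
                prob = ap$class_probs)
  extra <- stats::runif(n) < ap$extra_class
  cls2 <- vapply(seq_len(n), function(i) {
    if (!extra[i]) return(cls[i])
    other <- setdiff(names(ap$class_probs), cls[i])
    paste(sort(c(cls[i], sample(other, 1L))), collapse = ",")
  }, character(1L))
  out <- data.frame(admission_date = dates,
                    age = round(age),
                    sex = sex,
                    cvd_classes = cls2,
                    comorbidity = stats::runif(n) < ap$comorbidity,
                    days_in_hospital = stats::rgeom(n, ap$stay_geom_p) + 1L)
  attr(out, "daily") <- data.frame(date = cum$date[ok], lambda = lam,
                                   count = counts)
  class(out) <- c("case_records", "data.frame")
  out
}

#' Aggregate case records to daily death counts
#' @param cases A `case_records` data frame.
#' @param dates Optional vector of dates to cover (days with no case get
#'   a zero count); defaults to the span of the case dates.
#' @return Data frame `date, deaths`.
#' @export
daily_death_counts <- function(cases, dates = NULL) {
  d <- as.Date(cases$admission_date)
  if (is.null(dates))
    dates <- if (length(d)) seq(min(d), max(d), by = "day") else as.Date(character())
  cnt <- tabulate(match(d, dates), nbins = length(dates))
  data.frame(date = dates, deaths = cnt)
}

#' Read case records from CSV
#' @param path CSV with header
#'   `admission_date,age,sex,cvd_classes,comorbidity,days_in_hospital`.
#' @return A `case_records` data frame.
#' @export
read_cases_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cvd_classes = "character"))
  df$admission_date <- as.Date(df$admission_date)
  df$comorbidity <- as.logical(df$comorbidity)
  class(df) <- c("case_records", "data.frame")
  df
}

#' Write a self-contained fixture bundle
#'
#' Writes `weather.csv`, `cases.csv`, `truth.json` and `spec.yaml` to a
#' directory so a full analysis can be replayed from files alone. The
#' truth file records the generating surface and the true attributable
#' fractions computed from it.
#'
#' @param dir Output directory (created if needed).
#' @param climate A [climate_spec()].
#' @param surface A [surface_spec()].
#' @param baseline_rate Expected deaths/day at the MMT.
#' @param case_seed Seed for the case simulator.
#' @param max_gap Gap-fill policy passed to [build_regional_series()].
#' @return Invisibly, a list with the in-memory `weather`, `tapp`,
#'   `cases` and `truth` objects.
#' @export
write_fixture_bundle <- function(dir, climate = climate_spec(),
                                 surface = surface_spec(),
                                 baseline_rate = 1.1, case_seed = 2L,
                                 max_gap = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  weather <- simulate_weather(climate)
  tapp <- build_regional_series(weather, max_gap = max_gap)
  cases <- simulate_cases(tapp, surface, baseline_rate, seed = case_seed)
  truth <- c(true_attributable(surface, tapp, baseline_rate),
             list(mmt_true = surface$mmt_true,
                  baseline_rate = baseline_rate,
                  surface = unclass(surface)))
  wdf <- weather; wdf$date <- format(wdf$date)
  utils::write.csv(wdf, file.path(dir, "weather.csv"),
                   row.names = FALSE, quote = FALSE)
  cdf <- as.data.frame(cases); cdf$admission_date <- format(cdf$admission_date)
  cdf$comorbidity <- tolower(as.character(cdf$comorbidity))
  utils::write.csv(cdf, file.path(dir, "cases.csv"),
                   row.names = FALSE, quote = TRUE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(list(climate = lapply(unclass(climate), as.character),
                        surface = unclass(surface),
                        baseline_rate = baseline_rate,
                        case_seed = case_seed, max_gap = max_gap),
                   file.path(dir, "spec.yaml"))
  invisible(list(weather = weather, tapp = tapp, cases = cases,
                 truth = truth))
}

#' Read a fixture bundle back
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with `weather`, `cases`, `truth`.
#' @export
read_fixture_bundle <- function(dir) {
  list(weather = read_weather_csv(file.path(dir, "weather.csv")),
       cases = read_cases_csv(file.path(dir, "cases.csv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
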