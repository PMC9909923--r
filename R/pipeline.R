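#' Assemble and validate a run configuration
#'
#' One object drives an end-to-end analysis: paths, study period,
#' crossbasis settings, MMT restriction, attribution settings, subgroup
#' toggles and the sensitivity battery.
#'
#' @param weather_csv,cases_csv Input paths (see [read_weather_csv()],
#'   [read_cases_csv()]).
#' @param output_dir Output directory, or `NULL` to skip writing files.
#' @param study_start,study_end Study period (cases outside are dropped).
#'   Defaults to the span of the case dates.
#' @param exposure_knot_percentiles Percentiles (0-100) for the exposure
#'   spline's internal knots.
#' @param lag_knots Number of internal lag knots (log-spaced).
#' @param max_lag Lag window in days.
#' @param max_gap Weather gap-fill policy (days).
#' @param ws_unit Wind-speed unit in the weather file.
#' @param mmt_restrict Percentile pair bounding the MMT search.
#' @param n_replicates,seed Monte Carlo settings for the attribution CIs.
#' @param subgroups Character vector among `"age-sex"`, `"cvd-class"`.
#' @param age_cut Age cut for the age-sex strata: "below" is strictly
#'   less than the cut, "over" is greater or equal.
#' @return A validated `run_config` list.
#' @export
run_config <- function(weather_csv, cases_csv, output_dir = NULL,
                       study_start = NULL, study_end = NULL,
                       exposure_knot_percentiles = c(25, 75),
                       lag_knots = 3L, max_lag = 21L, max_gap = 3L,
                       ws_unit = "ms", mmt_restrict = c(2.5, 97.5),
                       n_replicates = 1000L, seed = 1L,
                       subgroups = c("age-sex", "cvd-class"),
                       age_cut = 60) {
  if (!file.exists(weather_csv)) stop("weather file not found: ", weather_csv)
  if (!file.exists(cases_csv)) stop("cases file not found: ", cases_csv)
  p <- exposure_knot_percentiles
  if (any(p <= 0 | p >= 100) || is.unsorted(p, strictly = TRUE))
    stop("exposure knot percentiles must be increasing and inside (0, 100)")
  if (max_lag < 1) stop("max_lag must be >= 1")
  structure(list(weather_csv = weather_csv, cases_csv = cases_csv,
                 output_dir = output_dir,
                 study_start = study_start, study_end = study_end,
                 exposure_knot_percentiles = p, lag_knots = lag_knots,
                 max_lag = max_lag, max_gap = max_gap, ws_unit = ws_unit,
                 mmt_restrict = mmt_restrict,
                 n_replicates = n_replicates, seed = seed,
                 subgroups = subgroups, age_cut = age_cut),
            class = "run_config")
}

#' Filter cases into a subgroup
#'
#' Age-and-sex strata partition the cases (after excluding those with
#' missing age or sex, which only leave the stratified runs); CVD-class
#' selection is overlapping by design: a case recorded with several
#' classes appears in every class it presented with (died *with*, not
#' necessarily *from*, that class).
#'
#' @param cases A `case_records` data frame.
#' @param rule `"age-sex"` or `"cvd-class"`.
#' @param level For age-sex: one of `"M<60", "M>=60", "F<60", "F>=60"`
#'   (with the configured cut in place of 60). For cvd-class: `"IHD"`,
#'   `"CVA"` or `"OTHER"`.
#' @param age_cut Age cut (default 60); "below" means strictly less.
#' @return The filtered `case_records`.
#' @export
subgroup_filter <- function(cases, rule = c("age-sex", "cvd-class"),
                            level, age_cut = 60) {
  rule <- match.arg(rule)
  if (rule == "age-sex") {
    lv <- c(sprintf("M<%s", age_cut), sprintf("M>=%s", age_cut),
            sprintf("F<%s", age_cut), sprintf("F>=%s", age_cut))
    if (!level %in% lv)
      stop("unknown age-sex level '", level, "'; expected one of ",
           paste(lv, collapse = ", "))
    sex <- substr(level, 1L, 1L)
    below <- grepl("<", level, fixed = TRUE)
    keep <- !is.na(cases$age) & cases$sex == sex &
      (if (below) cases$age < age_cut else cases$age >= age_cut)
  } else {
    if (!level %in% c("IHD", "CVA", "OTHER"))
      stop("unknown CVD class '", level, "'")
    keep <- vapply(strsplit(as.character(cases$cvd_classes), ","),
                   function(v) level %in% trimws(v), logical(1L))
  }
  out <- cases[keep, , drop = FALSE]
  class(out) <- class(cases)
  out
}

fit_one_stratum <- function(label, cases, cb, config, log) {
  if (nrow(cases) == 0L) {
    log(paste0("subgroup ", label, ": 0 cases, skipped"))
    return(NULL)
  }
  strata <- make_strata(cases)
  fit <- withCallingHandlers(
    fit_conditional(strata, cb),
    warning = function(w) { log(paste0(label, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning") })
  if (!fit$converged) stop("stage fit (", label, "): did not converge")
  mmt <- find_mmt(fit, cb, restrict = config$mmt_restrict)
  deaths <- daily_death_counts(cases, dates = attr(cb, "series")$date)
  att <- attribution(fit, cb, deaths, mmt$mmt,
                     n_replicates = config$n_replicates, seed = config$seed)
  curve <- cumulative_curve(fit, cb, center = mmt$mmt,
                            restrict = config$mmt_restrict)
  log(paste0("subgroup ", label, ": ", nrow(cases), " cases, ",
             fit$n_strata, " strata (", fit$n_dropped_strata, " dropped), ",
             "MMT ", sprintf("%.1f", mmt$mmt),
             ", AF ", sprintf("%.3f", att$af_total)))
  list(label = label, n_cases = nrow(cases), fit = fit, mmt = mmt,
       attribution = att, curve = curve)
}

#' Run the full analysis pipeline
#'
#' Ingestion, regional apparent-temperature construction, referent
#' matching, crossbasis, conditional-likelihood fit, MMT, curves and
#' attribution — for the overall data and every configured subgroup.
#' Artifacts (curve CSVs, a structured summary JSON, a line log) are
#' written when `output_dir` is set.
#'
#' @param config A [run_config()].
#' @return A `run_summary`: list with `overall` and per-subgroup results
#'   (each holding `mmt`, `attribution`, `curve`, counts), the dropped /
#'   excluded case bookkeeping, the configuration and a log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  log <- function(msg) log_lines[[length(log_lines) + 1L]] <<- msg

  weather <- read_weather_csv(config$weather_csv, ws_unit = config$ws_unit)
  cases <- read_cases_csv(config$cases_csv)
  n_read <- nrow(cases)
  if (!is.null(config$study_start))
    cases <- cases[cases$admission_date >= as.Date(config$study_start), ]
  if (!is.null(config$study_end))
    cases <- cases[cases$admission_date <= as.Date(config$study_end), ]
  log(paste0("cases read: ", n_read, "; in study period: ", nrow(cases)))
  if (nrow(cases) == 0L) stop("stage ingest: no cases in the study period")

  tapp <- build_regional_series(weather, max_gap = config$max_gap)
  cb <- build_crossbasis(
    tapp,
    exposure_spec = default_exposure_spec(
      tapp, config$exposure_knot_percentiles),
    lag_spec = default_lag_spec(config$max_lag, config$lag_knots),
    max_lag = config$max_lag)

  groups <- list(overall = cases)
  if ("age-sex" %in% config$subgroups) {
    for (lv in c(sprintf("M<%s", config$age_cut),
                 sprintf("M>=%s", config$age_cut),
                 sprintf("F<%s", config$age_cut),
                 sprintf("F>=%s", config$age_cut)))
      groups[[lv]] <- subgroup_filter(cases, "age-sex", lv, config$age_cut)
    n_excl <- sum(is.na(cases$age) | !cases$sex %in% c("M", "F"))
    log(paste0("age-sex runs exclude ", n_excl,
               " case(s) with missing age or sex"))
  }
  if ("cvd-class" %in% config$subgroups)
    for (lv in c("IHD", "CVA", "OTHER"))
      groups[[lv]] <- subgroup_filter(cases, "cvd-class", lv)

  results <- list()
  for (label in names(groups)) {
    res <- fit_one_stratum(label, groups[[label]], cb, config, log)
    if (!is.null(res)) results[[label]] <- res
  }

  summary <- structure(
    list(strata = results, tapp_summary = tapp_summary(tapp),
         config = unclass(config), log = log_lines,
         n_cases_total = nrow(cases)),
    class = "run_summary")
  if (!is.null(config$output_dir)) write_run_summary(summary, config$output_dir)
  summary
}

write_run_summary <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (label in names(summary$strata)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", label)
    write_curve_csv(summary$strata[[label]]$curve,
                    file.path(dir, paste0("curve_", safe, ".csv")))
  }
  slim <- lapply(summary$strata, function(s)
    list(label = s$label, n_cases = s$n_cases,
         mmt = unclass(s$mmt),
         attribution = unclass(s$attribution)[c(
           "af_total", "af_cold", "af_heat", "an_total", "an_cold",
           "an_heat", "ci", "n_replicates", "seed", "mmt")]))
  jsonlite::write_json(list(strata = slim,
                            tapp_summary = summary$tapp_summary,
                            n_cases_total = summary$n_cases_total),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(summary$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Sensitivity battery
#'
#' Re-runs the overall analysis under (a) four alternative exposure-knot
#' placements (2 equally spaced; 5/50/95; 25/50/75; 5/95 percentiles),
#' (b) the quasi-Poisson time-series path, (c) a length-of-stay filter
#' (hospital stay of at most `stay_max` days), and (d) a restricted date
#' range, and reports each variant's cumulative curve on the base grid
#' together with the maximum pointwise RR divergence from the base curve.
#'
#' @param config A [run_config()].
#' @param stay_max Length-of-stay cutoff in days (default 10).
#' @param date_range Optional `c(start, end)` for the restricted-period
#'   rerun; default is the most recent half of the study span.
#' @return A list with `base` (overall result), `variants` (named list of
#'   curves + MMT + AF), and `divergence` (data frame of max pointwise
#'   |RR difference| per variant).
#' @export
sensitivity_suite <- function(config, stay_max = 10, date_range = NULL) {
  stopifnot(inherits(config, "run_config"))
  weather <- read_weather_csv(config$weather_csv, ws_unit = config$ws_unit)
  cases <- read_cases_csv(config$cases_csv)
  tapp <- build_regional_series(weather, max_gap = config$max_gap)
  lag_spec <- default_lag_spec(config$max_lag, config$lag_knots)
  base_cb <- build_crossbasis(
    tapp, exposure_spec = default_exposure_spec(
      tapp, config$exposure_knot_percentiles),
    lag_spec = lag_spec, max_lag = config$max_lag)
  strata <- make_strata(cases)
  base_fit <- suppressWarnings(fit_conditional(strata, base_cb))
  base_mmt <- find_mmt(base_fit, base_cb, restrict = config$mmt_restrict)
  grid <- cumulative_curve(base_fit, base_cb, base_mmt$mmt,
                           restrict = config$mmt_restrict)
  deaths <- daily_death_counts(cases, dates = tapp$date)

  variants <- list()
  refit_knots <- function(pcts) {
    cbv <- build_crossbasis(
      tapp, exposure_spec = default_exposure_spec(tapp, pcts),
      lag_spec = lag_spec, max_lag = config$max_lag)
    fitv <- suppressWarnings(fit_conditional(strata, cbv))
    mm <- find_mmt(fitv, cbv, restrict = config$mmt_restrict)
    list(curve = cumulative_curve(fitv, cbv, mm$mmt,
                                  grid = grid$exposure_c),
         mmt = mm,
         af = attributable(fitv, cbv, deaths, mm$mmt, "all")$af)
  }
  variants[["knots_2_equal"]] <- refit_knots(c(100 / 3, 200 / 3))
  variants[["knots_5_50_95"]] <- refit_knots(c(5, 50, 95))
  variants[["knots_25_50_75"]] <- refit_knots(c(25, 50, 75))
  variants[["knots_5_95"]] <- refit_knots(c(5, 95))

  qp_fit <- fit_quasipoisson(deaths, base_cb)
  qp_mmt <- find_mmt(qp_fit, base_cb, restrict = config$mmt_restrict)
  variants[["quasipoisson"]] <- list(
    curve = cumulative_curve(qp_fit, base_cb, qp_mmt$mmt,
                             grid = grid$exposure_c),
    mmt = qp_mmt,
    af = attributable(qp_fit, base_cb, deaths, qp_mmt$mmt, "all")$af,
    dispersion = qp_fit$dispersion)

  refit_cases <- function(sub) {
    if (nrow(sub) == 0L) return(NULL)
    fitv <- suppressWarnings(fit_conditional(make_strata(sub), base_cb))
    mm <- find_mmt(fitv, base_cb, restrict = config$mmt_restrict)
    dd <- daily_death_counts(sub, dates = tapp$date)
    list(curve = cumulative_curve(fitv, base_cb, mm$mmt,
                                  grid = grid$exposure_c),
         mmt = mm, af = attributable(fitv, base_cb, dd, mm$mmt, "all")$af)
  }
  short <- cases[cases$days_in_hospital <= stay_max, , drop = FALSE]
  class(short) <- class(cases)
  variants[["stay_le_10"]] <- refit_cases(short)
  if (is.null(date_range)) {
    span <- range(cases$admission_date)
    date_range <- c(span[1L] + as.numeric(diff(span)) %/% 2, span[2L])
  }
  sub5 <- cases[cases$admission_date >= as.Date(date_range[1L]) &
                  cases$admission_date <= as.Date(date_range[2L]), ,
                drop = FALSE]
  class(sub5) <- class(cases)
  variants[["date_restricted"]] <- refit_cases(sub5)

  divergence <- data.frame(
    variant = names(variants),
    max_rr_divergence = vapply(variants, function(v)
      if (is.null(v)) NA_real_ else max(abs(v$curve$rr - grid$rr)),
      numeric(1L)),
    row.names = NULL)
  list(base = list(curve = grid, mmt = base_mmt,
                   af = attributable(base_fit, base_cb, deaths,
                                     base_mmt$mmt, "all")$af),
       variants = variants, divergence = divergence)
}
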