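#' Saturation-scaled water vapour pressure
#'
#' Computes the water vapour pressure (hPa) from dry-bulb temperature and
#' relative humidity using the Magnus-type form employed in Steadman's
#' apparent-temperature equation:
#' \deqn{hPa = \frac{RH}{100} \times 6.105 \times
#'       e^{\,17.27\,Ta / (237.7 + Ta)}}
#'
#' @param ta Dry-bulb temperature in degrees Celsius. Must exceed -237.7.
#' @param rh Relative humidity in percent, in \[0, 100\].
#' @return Vapour pressure in hPa, same length as the inputs (which are
#'   recycled by the usual rules).
#' @examples
#' vapour_pressure(30, 100)
#' vapour_pressure(28.6, 76.6)
#' @export
vapour_pressure <- function(ta, rh) {
  if (any(!is.finite(ta)) || any(!is.finite(rh)))
    stop("vapour_pressure: non-finite temperature or humidity")
  bad <- rh < 0 | rh > 100
  if (any(bad))
    stop("vapour_pressure: relative humidity outside [0, 100] at position(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  if (any(ta <= -237.7))
    stop("vapour_pressure: temperature at or below -237.7 C")
  (rh / 100) * 6.105 * exp(17.27 * ta / (237.7 + ta))
}

#' Steadman apparent temperature
#'
#' The physiologically weighted "felt" temperature combining dry-bulb
#' temperature, humidity (through vapour pressure) and wind speed:
#' \deqn{T_{app} = Ta + 0.33 \times hPa - 0.7 \times WS - 4}
#'
#' @param ta Dry-bulb temperature, degrees Celsius.
#' @param rh Relative humidity, percent.
#' @param ws Wind speed, metres per second (non-negative).
#' @return Apparent temperature in degrees Celsius.
#' @examples
#' apparent_temperature(30, 100, 0)
#' apparent_temperature(ta = 28.6, rh = 76.6, ws = 1.4)
#' @export
apparent_temperature <- function(ta, rh, ws) {
  if (any(!is.finite(ws)) || any(ws < 0))
    stop("apparent_temperature: wind speed must be finite and >= 0")
  ta + 0.33 * vapour_pressure(ta, rh) - 0.7 * ws - 4
}

#' Read station weather records from CSV
#'
#' Expects columns `date,station_id,ta_c,rh_pct,ws_ms` with ISO-8601 dates.
#' Duplicate (station, day) pairs are rejected. Wind speed recorded in km/h
#' at the source can be converted on the way in.
#'
#' @param path Path to the CSV file.
#' @param ws_unit Unit of the wind-speed column: `"ms"` (default) or
#'   `"kmh"`, in which case values are divided by 3.6.
#' @return A data frame of weather records with columns `date` (Date),
#'   `station_id`, `ta_c`, `rh_pct`, `ws_ms`.
#' @export
read_weather_csv <- function(path, ws_unit = c("ms", "kmh")) {
  ws_unit <- match.arg(ws_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "station_id", "ta_c", "rh_pct", "ws_ms")
  if (!all(need %in% names(df)))
    stop("weather CSV must have columns: ", paste(need, collapse = ","))
  df$date <- as.Date(df$date)
  if (ws_unit == "kmh") df$ws_ms <- df$ws_ms / 3.6
  validate_weather(df)
}

#' @keywords internal
validate_weather <- function(df) {
  if (nrow(df) == 0L) stop("weather data is empty")
  if (any(is.na(df$date))) stop("weather data: unparseable dates")
  dup <- duplicated(df[c("station_id", "date")])
  if (any(dup))
    stop("duplicate weather record for station ", df$station_id[dup][1L],
         " on ", format(df$date[dup][1L]))
  if (any(df$rh_pct < 0 | df$rh_pct > 100, na.rm = TRUE))
    stop("weather data: relative humidity outside [0, 100] (station ",
         df$station_id[which(df$rh_pct < 0 | df$rh_pct > 100)[1L]], ")")
  if (any(df$ws_ms < 0, na.rm = TRUE))
    stop("weather data: negative wind speed")
  df
}

#' Build the regional daily apparent-temperature series
#'
#' Computes apparent temperature per station-day, then averages across the
#' stations reporting on each calendar day, producing one regional series.
#' Days with no station at all are linearly interpolated when the gap is at
#' most `max_gap` consecutive days; longer gaps are left missing (`NA`) and
#' will exclude any lag window that touches them downstream.
#'
#' @param records Weather records as returned by [read_weather_csv()] (or
#'   any data frame with the same columns).
#' @param max_gap Longest run of empty days to fill by linear
#'   interpolation; default 3.
#' @return A `tapp_series` data frame with columns `date`, `tapp_c`,
#'   `n_stations` covering the full span of the input dates, one row per
#'   day. `n_stations` is 0 on interpolated or missing days.
#' @export
build_regional_series <- function(records, max_gap = 3L) {
  records <- validate_weather(as.data.frame(records))
  tapp <- apparent_temperature(records$ta_c, records$rh_pct, records$ws_ms)
  day <- records$date
  span <- seq(min(day), max(day), by = "day")
  idx <- match(day, span)
  sums <- tapply(tapp, idx, sum)
  cnts <- tapply(tapp, idx, length)
  out <- data.frame(date = span, tapp_c = NA_real_,
                    n_stations = 0L)
  pos <- as.integer(names(sums))
  out$tapp_c[pos] <- as.numeric(sums) / as.numeric(cnts)
  out$n_stations[pos] <- as.integer(cnts)
  out$tapp_c <- fill_short_gaps(out$tapp_c, max_gap)
  class(out) <- c("tapp_series", "data.frame")
  out
}

# Linear interpolation of interior NA runs of length <= max_gap; leading or
# trailing NAs and longer runs are left untouched.
fill_short_gaps <- function(x, max_gap) {
  if (!anyNA(x) || max_gap < 1L) return(x)
  n <- length(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == n) next                    # no anchor on one side
    a <- x[i0 - 1L]; b <- x[i1 + 1L]
    if (is.na(a) || is.na(b)) next
    w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1L)
    x[i0:i1] <- a + w * (b - a)
  }
  x
}

#' Summary statistics of an apparent-temperature series
#'
#' @param series A `tapp_series`.
#' @param probs Percentiles to report (fractions).
#' @return A list with mean, sd, min, max and the requested percentiles of
#'   the non-missing daily values, plus counts of days and missing days.
#' @export
tapp_summary <- function(series,
                         probs = c(0.025, 0.05, 0.25, 0.5, 0.75, 0.95, 0.975)) {
  x <- series$tapp_c[!is.na(series$tapp_c)]
  list(n_days = nrow(series),
       n_missing = sum(is.na(series$tapp_c)),
       mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
       percentiles = as.list(stats::setNames(
         stats::quantile(x, probs, names = FALSE), paste0("p", probs * 100))))
}

#' Write the regional series and its summary
#'
#' Writes `date,tapp_c,n_stations` as CSV and, optionally, a JSON summary
#' produced by [tapp_summary()].
#'
#' @param series A `tapp_series`.
#' @param path Output CSV path.
#' @param summary_path Optional JSON summary path.
#' @return Invisibly, `path`.
#' @export
write_tapp_series <- function(series, path, summary_path = NULL) {
  df <- as.data.frame(series)
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(tapp_summary(series), summary_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a regional series written by [write_tapp_series()]
#' @param path CSV path with columns `date,tapp_c,n_stations`.
#' @return A `tapp_series` data frame.
#' @export
read_tapp_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  class(df) <- c("tapp_series", "data.frame")
  df
}
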