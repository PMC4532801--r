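#' Construct a temperature series
#'
#' A temperature series is the package's container for timestamped
#' temperature-logger or station readings: a data frame with columns
#' `timestamp` (POSIXct, treated as local civil time with no DST arithmetic),
#' `temp_c` and optionally `snow_depth_cm`, carrying `cadence` and
#' `site_label` attributes. Hourly logger traces and thrice-daily station
#' readings (0600/1200/1800) are the two structured cadences; anything else
#' is `"irregular"`.
#'
#' @param timestamp POSIXct (or ISO 8601 character) timestamps, strictly
#'   increasing.
#' @param temp_c numeric temperatures in degrees Celsius, finite and within
#'   \[-60, 60\].
#' @param snow_depth_cm optional non-negative snow depths (NA allowed).
#' @param cadence one of `"hourly"`, `"thrice_daily"`, `"irregular"`, or
#'   `NULL` to detect from the median spacing.
#' @param site_label free-text site identifier.
#' @return A `temperature_series` data frame.
#' @export
temperature_series <- function(timestamp, temp_c, snow_depth_cm = NULL,
                               cadence = NULL, site_label = "") {
  if (is.character(timestamp)) timestamp <- parse_timestamp(timestamp)
  if (!inherits(timestamp, "POSIXct")) {
    stop_contract("`timestamp` must be POSIXct or ISO 8601 character")
  }
  attr(timestamp, "tzone") <- "UTC"
  n <- length(timestamp)
  if (n == 0L) stop_contract("empty temperature series")
  if (length(temp_c) != n) stop_contract("timestamp/temp_c length mismatch")
  if (anyNA(timestamp)) stop_contract("missing timestamps")
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    stop_contract("timestamps must be strictly increasing")
  }
  bad <- !is.finite(temp_c) | temp_c < -60 | temp_c > 60
  if (any(bad)) {
    stop_contract("temp_c must be finite and within [-60, 60] (first bad row: %d)",
                  which(bad)[1])
  }
  if (!is.null(snow_depth_cm)) {
    if (length(snow_depth_cm) != n) stop_contract("snow_depth_cm length mismatch")
    if (any(snow_depth_cm < 0, na.rm = TRUE)) {
      stop_contract("snow_depth_cm must be >= 0")
    }
  }
  cadence <- cadence %||% detect_cadence(timestamp)
  cadence <- match.arg(cadence, c("hourly", "thrice_daily", "irregular"))
  out <- data.frame(timestamp = timestamp, temp_c = as.numeric(temp_c))
  if (!is.null(snow_depth_cm)) out$snow_depth_cm <- as.numeric(snow_depth_cm)
  structure(out,
            cadence = cadence, site_label = site_label,
            class = c("temperature_series", "data.frame"))
}

parse_timestamp <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- rep(NA_real_, length(x))
  for (f in fmts) {
    na <- is.na(out)
    if (!any(na)) break
    p <- strptime(x[na], f, tz = "UTC")
    out[na] <- as.numeric(as.POSIXct(p, tz = "UTC"))
  }
  if (anyNA(out)) {
    stop_contract("unparseable timestamp at row %d: '%s'",
                  which(is.na(out))[1], x[which(is.na(out))[1]])
  }
  as.POSIXct(out, origin = "1970-01-01", tz = "UTC")
}

detect_cadence <- function(timestamp) {
  if (length(timestamp) < 3L) return("irregular")
  dt <- diff(as.numeric(timestamp))
  if (abs(stats::median(dt) - 3600) < 1) return("hourly")
  hrs <- as.integer(format(timestamp, "%H", tz = "UTC"))
  mins <- as.integer(format(timestamp, "%M", tz = "UTC"))
  if (all(hrs %in% c(6L, 12L, 18L)) && all(mins == 0L)) return("thrice_daily")
  "irregular"
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> %d readings, cadence %s%s\n",
              nrow(x), attr(x, "cadence"),
              if (nzchar(attr(x, "site_label")))
                paste0(", site '", attr(x, "site_label"), "'") else ""))
  cat(sprintf("  %s .. %s, temp %.1f .. %.1f C\n",
              format(x$timestamp[1]), format(x$timestamp[nrow(x)]),
              min(x$temp_c), max(x$temp_c)))
  invisible(x)
}

#' Read a temperature CSV
#'
#' Expects columns `timestamp` (ISO 8601), `temp_c`, and optionally
#' `snow_depth_cm`. Rows are sorted by timestamp; duplicated timestamps are
#' collapsed to their mean with a warning.
#'
#' @param path path to a CSV file.
#' @param cadence_hint optional cadence to record instead of auto-detection.
#' @return A [temperature_series()].
#' @export
read_temperature_csv <- function(path, cadence_hint = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_contract("empty temperature file: %s", path)
  need <- c("timestamp", "temp_c")
  if (!all(need %in% names(df))) {
    stop_contract("temperature CSV must have columns %s",
                  paste(need, collapse = ", "))
  }
  ts <- parse_timestamp(as.character(df$timestamp))
  df$timestamp <- ts
  df <- df[order(df$timestamp), , drop = FALSE]
  if (anyDuplicated(df$timestamp)) {
    warning("duplicate timestamps collapsed to their mean", call. = FALSE)
    key <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    agg <- function(v) as.numeric(tapply(v, key, mean, na.rm = TRUE))
    uts <- df$timestamp[!duplicated(key)]
    o <- order(uts)
    temp <- agg(df$temp_c)
    snow <- if ("snow_depth_cm" %in% names(df)) agg(df$snow_depth_cm) else NULL
    # tapply sorts by key string, which sorts chronologically for ISO format
    df <- data.frame(timestamp = sort(uts), temp_c = temp)
    if (!is.null(snow)) df$snow_depth_cm <- snow
  }
  temperature_series(df$timestamp, df$temp_c,
                     snow_depth_cm = df[["snow_depth_cm"]],
                     cadence = cadence_hint)
}

#' Write a temperature series to CSV
#'
#' Values are printed at a fixed decimal precision; a file written and re-read
#' round-trips bit-identically at that precision.
#'
#' @param series a [temperature_series()].
#' @param path output path.
#' @param digits decimal places for temperatures and depths.
#' @export
write_temperature_csv <- function(series, path, digits = 3) {
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temp_c = formatC(series$temp_c, digits = digits, format = "f"))
  if ("snow_depth_cm" %in% names(series)) {
    out$snow_depth_cm <- formatC(series$snow_depth_cm, digits = digits,
                                 format = "f")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily mean temperatures
#'
#' Aggregates a temperature series to one row per calendar date with the
#' arithmetic mean of that date's included readings.
#'
#' Under the `thrice_daily` policy (the station convention) the daily mean is
#' the mean of the 0600, 1200 and 1800 readings and a day is `complete` only
#' when all three are present. Under the `hourly` policy gaps of up to
#' `max_gap_h` hours are linearly interpolated before aggregation (logger
#' dropouts are common and short gaps are benign at diurnal scale); a day is
#' `complete` when at least 20 of its 24 hourly slots are covered. Incomplete
#' days are flagged, never dropped.
#'
#' @param series a [temperature_series()].
#' @param policy `"auto"` (use the series cadence), `"hourly"` or
#'   `"thrice_daily"`.
#' @param max_gap_h maximum hourly gap to interpolate (hourly policy).
#' @return data frame with columns `date`, `daily_mean_c`, `n_readings`,
#'   `complete`.
#' @export
daily_means <- function(series, policy = c("auto", "hourly", "thrice_daily"),
                        max_gap_h = 6) {
  policy <- match.arg(policy)
  if (policy == "auto") {
    policy <- switch(attr(series, "cadence"),
                     hourly = "hourly",
                     thrice_daily = "thrice_daily",
                     "hourly")
  }
  if (nrow(series) == 0L) stop_contract("empty series")
  if (policy == "thrice_daily") {
    hrs <- as.integer(format(series$timestamp, "%H", tz = "UTC"))
    keep <- hrs %in% c(6L, 12L, 18L)
    sub <- series[keep, , drop = FALSE]
    date <- as.Date(sub$timestamp, tz = "UTC")
    all_dates <- sort(unique(as.Date(series$timestamp, tz = "UTC")))
    mean_by <- tapply(sub$temp_c, as.character(date), mean)
    n_by <- tapply(sub$temp_c, as.character(date), length)
    key <- as.character(all_dates)
    n <- ifelse(key %in% names(n_by), n_by[key], 0L)
    m <- ifelse(key %in% names(mean_by), mean_by[key], NA_real_)
    out <- data.frame(date = all_dates,
                      daily_mean_c = as.numeric(m),
                      n_readings = as.integer(n),
                      complete = as.integer(n) == 3L)
    rownames(out) <- NULL
    return(out)
  }
  # hourly policy: snap readings onto the hourly grid spanning the series,
  # interpolate short gaps, then aggregate by date
  t0 <- trunc(series$timestamp[1], units = "hours")
  t1 <- trunc(series$timestamp[nrow(series)], units = "hours")
  grid <- seq(t0, t1, by = 3600)
  slot <- as.integer(round(as.numeric(series$timestamp - t0, units = "hours"))) + 1L
  vals <- rep(NA_real_, length(grid))
  ok <- slot >= 1L & slot <= length(grid)
  vals[slot[ok]] <- series$temp_c[ok]
  observed <- !is.na(vals)
  vals <- fill_gaps(vals, max_gap = max_gap_h)
  gdate <- as.Date(grid, tz = "UTC")
  key <- as.character(gdate)
  ukey <- unique(key)
  covered <- tapply(!is.na(vals), key, sum)[ukey]
  nobs <- tapply(observed, key, sum)[ukey]
  m <- tapply(vals, key, mean, na.rm = TRUE)[ukey]
  m[covered == 0] <- NA_real_
  out <- data.frame(date = as.Date(ukey),
                    daily_mean_c = as.numeric(m),
                    n_readings = as.integer(nobs),
                    complete = as.integer(covered) >= 20L)
  rownames(out) <- NULL
  out
}

#' Define an autumn season window
#'
#' A month-day window within one calendar year, defaulting to 1 August --
#' 30 November, the interval between the earliest observed field germination
#' and typical snow onset in northern Sweden.
#'
#' @param start_month_day,end_month_day `"MM-DD"` strings, start before end.
#' @return A `season_window` list.
#' @export
season_window <- function(start_month_day = "08-01", end_month_day = "11-30") {
  chk <- function(x) {
    if (!grepl("^[0-1][0-9]-[0-3][0-9]$", x)) {
      stop_contract("month-day must be 'MM-DD', got '%s'", x)
    }
    x
  }
  s <- chk(start_month_day); e <- chk(end_month_day)
  if (s >= e) stop_contract("season start must precede end within a year")
  structure(list(start_month_day = s, end_month_day = e),
            class = "season_window")
}

in_season <- function(dates, season) {
  md <- format(dates, "%m-%d")
  md >= season$start_month_day & md <= season$end_month_day
}

#' Autumn temperature statistics
#'
#' Pools complete daily means over every season (calendar year) covered by
#' `dailies` and reports their mean and SD, the per-season means and their SD
#' (the statistic usually quoted for multi-year station records), and the
#' fraction of days whose daily mean lies strictly inside a vernalization
#' window.
#'
#' @param dailies output of [daily_means()].
#' @param season a [season_window()].
#' @param window a [vernalization_window()]; membership is strict at both
#'   bounds.
#' @return An `autumn_summary` list with fields `years_covered`,
#'   `mean_of_daily_means_c`, `sd_of_daily_means_c`, `season_means_c`,
#'   `sd_of_season_means_c`, `fraction_days_in_window`, `n_days`,
#'   `n_incomplete_days`, `window_used`.
#' @export
autumn_summary <- function(dailies, season = season_window(),
                           window = vernalization_window(0, 15, "daily_mean")) {
  sel <- in_season(dailies$date, season)
  d <- dailies[sel, , drop = FALSE]
  n_incomplete <- sum(!d$complete)
  d <- d[d$complete, , drop = FALSE]
  if (nrow(d) == 0L) stop_contract("no complete days in any season")
  yr <- as.integer(format(d$date, "%Y"))
  season_means <- tapply(d$daily_mean_c, yr, mean)
  inside <- d$daily_mean_c > window$lower_c & d$daily_mean_c < window$upper_c
  structure(list(
    years_covered = sort(unique(yr)),
    mean_of_daily_means_c = mean(d$daily_mean_c),
    sd_of_daily_means_c = stats::sd(d$daily_mean_c),
    season_means_c = as.numeric(season_means),
    sd_of_season_means_c = if (length(season_means) > 1)
      stats::sd(season_means) else NA_real_,
    fraction_days_in_window = mean(inside),
    n_days = nrow(d),
    n_incomplete_days = n_incomplete,
    window_used = window
  ), class = "autumn_summary")
}

#' @export
print.autumn_summary <- function(x, ...) {
  cat(sprintf("<autumn_summary> %d season(s): %s\n",
              length(x$years_covered),
              paste(range(x$years_covered), collapse = "-")))
  cat(sprintf("  mean of daily means %.2f C (pooled SD %.2f, between-season SD %s)\n",
              x$mean_of_daily_means_c, x$sd_of_daily_means_c,
              ifelse(is.na(x$sd_of_season_means_c), "NA",
                     sprintf("%.2f", x$sd_of_season_means_c))))
  cat(sprintf("  %.1f%% of %d complete days strictly inside (%g, %g) C\n",
              100 * x$fraction_days_in_window, x$n_days,
              x$window_used$lower_c, x$window_used$upper_c))
  invisible(x)
}

#' Detect snow cover from a soil-surface trace
#'
#' Insulating snow clamps the soil-surface temperature near 0 degrees C with
#' very low variability. Intervals are reported where every reading satisfies
#' `|temp_c| <= band_c` and the centred 24-h rolling SD is `<= sd_cap_c`, for
#' at least `min_run_h` hours. When a `snow_depth_cm` column is present,
#' intervals with depth > 0 are used directly instead.
#'
#' @param series a [temperature_series()] recorded at the soil surface.
#' @param band_c half-width of the temperature band around 0 degrees C.
#' @param sd_cap_c cap on the rolling SD.
#' @param min_run_h minimum run length in hours.
#' @return data frame with POSIXct columns `start`, `end` (possibly 0 rows),
#'   sorted and disjoint.
#' @export
detect_snow_cover <- function(series, band_c = 1.0, sd_cap_c = 0.5,
                              min_run_h = 72) {
  n <- nrow(series)
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"))
  if (n < 2L) return(empty)
  if ("snow_depth_cm" %in% names(series) && any(!is.na(series$snow_depth_cm))) {
    flag <- !is.na(series$snow_depth_cm) & series$snow_depth_cm > 0
  } else {
    dt_h <- stats::median(diff(as.numeric(series$timestamp))) / 3600
    k <- max(3L, round(24 / dt_h))
    if (k %% 2L == 0L) k <- k + 1L
    rsd <- roll_sd(series$temp_c, k)
    flag <- abs(series$temp_c) <= band_c & !is.na(rsd) & rsd <= sd_cap_c
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) return(empty)
  s <- series$timestamp[starts[keep]]
  e <- series$timestamp[ends[keep]]
  dur_h <- as.numeric(e - s, units = "hours")
  ok <- dur_h >= min_run_h
  if (!any(ok)) return(empty)
  data.frame(start = s[ok], end = e[ok])
}
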