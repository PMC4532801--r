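#' Define a vernalization temperature window
#'
#' A temperature interval within which time counts towards vernalization.
#' Membership is strict at both bounds (the legacy photothermal convention
#' "higher than 0 and lower than 6 degrees C"), applied identically at the
#' lower and upper threshold. The `basis` decides what is tested against the
#' window: individual hourly readings, or complete-day daily means.
#'
#' @param lower_c,upper_c window bounds in degrees C, `lower_c < upper_c`.
#' @param basis `"hourly"` or `"daily_mean"`.
#' @param daytime_only count only civil daylight hours (08:00--15:59,
#'   matching an 8-h cabinet photoperiod); permitted only with
#'   `basis = "hourly"`.
#' @return A `vernalization_window` list.
#' @export
vernalization_window <- function(lower_c, upper_c,
                                 basis = c("hourly", "daily_mean"),
                                 daytime_only = FALSE) {
  basis <- match.arg(basis)
  if (!is.finite(lower_c) || !is.finite(upper_c) || lower_c >= upper_c) {
    stop_contract("window requires lower_c < upper_c")
  }
  if (daytime_only && basis != "hourly") {
    stop_contract("daytime_only is permitted only with basis = 'hourly'")
  }
  structure(list(lower_c = lower_c, upper_c = upper_c, basis = basis,
                 daytime_only = daytime_only),
            class = "vernalization_window")
}

#' @export
print.vernalization_window <- function(x, ...) {
  cat(sprintf("<vernalization_window> (%g, %g) C, basis %s%s\n",
              x$lower_c, x$upper_c, x$basis,
              if (x$daytime_only) ", daytime only" else ""))
  invisible(x)
}

DAYTIME_HOURS <- 8:15  # 08:00-15:59 civil time
HOURS_PER_WEEK <- 168

#' Accumulate vernalization-effective time
#'
#' Counts time spent inside a vernalization window. Under the hourly basis
#' each hourly reading with `lower < T < upper` contributes one hour
#' (restricted to 08:00--15:59 if the window is daytime-only). Under the
#' daily-mean basis each complete day whose daily mean lies strictly inside
#' the window contributes 24 hours; incomplete days contribute nothing.
#' Effective weeks are hours / 168 under both bases, which makes the two
#' bases commensurable and makes accumulation at a constant in-window
#' temperature exactly linear (1 week of elapsed time per effective week).
#'
#' @param x a [temperature_series()] with hourly cadence (hourly basis) or a
#'   [daily_means()] data frame (daily-mean basis).
#' @param window a [vernalization_window()].
#' @param reference_temp_c optional constant reference temperature; when
#'   given (and inside the window) a `reference_weeks` column is attached
#'   with the accumulation a constant-temperature condition would achieve,
#'   i.e. elapsed hours / 168.
#' @return An `accumulation_trace` data frame with columns `timestamp`,
#'   `effective_time_h`, `effective_weeks`, and optionally `reference_weeks`.
#' @export
accumulate <- function(x, window, reference_temp_c = NULL) {
  if (!inherits(window, "vernalization_window")) {
    stop_contract("`window` must be a vernalization_window")
  }
  if (window$basis == "hourly") {
    if (!inherits(x, "temperature_series")) {
      stop_contract("hourly basis requires a temperature_series")
    }
    if (attr(x, "cadence") != "hourly") {
      stop_contract("hourly basis requires hourly cadence, got '%s'",
                    attr(x, "cadence"))
    }
    ts <- x$timestamp
    eff <- x$temp_c > window$lower_c & x$temp_c < window$upper_c
    if (window$daytime_only) {
      hrs <- as.integer(format(ts, "%H", tz = "UTC"))
      eff <- eff & hrs %in% DAYTIME_HOURS
    }
    gain_h <- as.numeric(eff)  # 1 h per qualifying reading
    elapsed_h <- seq_along(ts) * 1.0
  } else {
    if (inherits(x, "temperature_series")) {
      stop_contract("daily_mean basis requires daily_means() output, not a temperature_series")
    }
    if (!all(c("date", "daily_mean_c", "complete") %in% names(x))) {
      stop_contract("daily_mean basis requires columns date, daily_mean_c, complete")
    }
    ts <- as.POSIXct(paste(x$date, "00:00:00"), tz = "UTC")
    eff <- x$complete & !is.na(x$daily_mean_c) &
      x$daily_mean_c > window$lower_c & x$daily_mean_c < window$upper_c
    gain_h <- 24 * as.numeric(eff)
    elapsed_h <- seq_along(ts) * 24.0
  }
  out <- data.frame(timestamp = ts,
                    effective_time_h = cumsum(gain_h))
  out$effective_weeks <- out$effective_time_h / HOURS_PER_WEEK
  if (!is.null(reference_temp_c)) {
    if (reference_temp_c <= window$lower_c || reference_temp_c >= window$upper_c) {
      stop_contract("reference temperature %g outside window (%g, %g): the reference would accumulate nothing",
                    reference_temp_c, window$lower_c, window$upper_c)
    }
    out$reference_weeks <- elapsed_h / HOURS_PER_WEEK
  }
  structure(out, window = window, reference_temp_c = reference_temp_c,
            class = c("accumulation_trace", "data.frame"))
}

#' Reference accumulation under a constant temperature
#'
#' The accumulation a constant-temperature condition would achieve over
#' \[start, end\]: elapsed hours / 168 weeks, provided the reference
#' temperature lies strictly inside the window (otherwise it would
#' accumulate zero, contradicting its role as the attainable maximum).
#'
#' @param start,end POSIXct or Date interval bounds, `start <= end`.
#' @param reference_temp_c constant temperature in degrees C.
#' @param window a [vernalization_window()].
#' @return cumulative effective weeks (scalar).
#' @export
reference_accumulation <- function(start, end, reference_temp_c, window) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (end < start) stop_contract("start must not exceed end")
  if (reference_temp_c <= window$lower_c || reference_temp_c >= window$upper_c) {
    stop_contract("reference temperature %g outside window (%g, %g)",
                  reference_temp_c, window$lower_c, window$upper_c)
  }
  as.numeric(end - start, units = "hours") / HOURS_PER_WEEK
}

#' First date at which a required accumulation is reached
#'
#' @param trace an [accumulate()] trace.
#' @param required_weeks positive number of effective weeks.
#' @return the first timestamp with `effective_weeks >= required_weeks`, or
#'   `NA` (with attribute `reached = FALSE`) if never reached.
#' @export
weeks_to_saturation <- function(trace, required_weeks) {
  if (required_weeks <= 0) stop_contract("required_weeks must be > 0")
  i <- which(trace$effective_weeks >= required_weeks)
  if (length(i) == 0L) {
    return(structure(as.POSIXct(NA, tz = "UTC"), reached = FALSE))
  }
  structure(trace$timestamp[i[1]], reached = TRUE)
}
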