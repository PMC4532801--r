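#' Time-weighted mean temperature over an interval
#'
#' Each reading is held constant until the next one (a logger sample
#' represents the hour it opens), so for a complete hourly record this is
#' exactly the arithmetic mean of the hourly values in `[start, end)`.
#' Coverage is the fraction of the interval not lost to edge gaps or
#' internal gaps longer than `max_gap_h`; below `min_coverage` an
#' insufficient-data error is raised.
#'
#' @param series a [temperature_series()].
#' @param start,end POSIXct (or coercible) interval bounds, `start < end`.
#' @param min_coverage minimum acceptable coverage fraction.
#' @param max_gap_h internal gaps up to this many hours are treated as
#'   covered (bridged by the held value).
#' @return mean temperature in degrees C, with a `coverage` attribute.
#' @export
interval_mean_temperature <- function(series, start, end,
                                      min_coverage = 0.8, max_gap_h = 6) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (end <= start) stop_contract("start must precede end")
  sel <- series$timestamp >= start & series$timestamp < end
  if (!any(sel)) stop_contract("no readings inside [%s, %s)", start, end)
  ts <- as.numeric(series$timestamp[sel])
  x <- series$temp_c[sel]
  hold <- if (length(ts) > 1) stats::median(diff(ts)) else 3600
  # each reading holds until the next one (capped at max_gap_h), the last
  # until min(its hold, end)
  dt <- c(diff(ts), min(hold, as.numeric(end) - ts[length(ts)]))
  covered <- pmin(dt, max_gap_h * 3600)
  span <- as.numeric(end) - as.numeric(start)
  uncovered <- (ts[1] - as.numeric(start)) + sum(dt - covered) +
    max(0, (as.numeric(end) - ts[length(ts)]) - dt[length(dt)])
  coverage <- max(0, 1 - uncovered / span)
  if (coverage < min_coverage) {
    stop_contract("interval coverage %.0f%% below required %.0f%%",
                  100 * coverage, 100 * min_coverage)
  }
  structure(sum(x * covered) / sum(covered), coverage = coverage)
}

#' Match a mean condition to the nearest cabinet grid cell
#'
#' The nearest grid temperature to the interval mean (ties to the lower
#' temperature) and the nearest grid duration (ties to the shorter).
#'
#' @param mean_temp_c interval mean temperature, degrees C.
#' @param duration_weeks interval duration, weeks.
#' @param surface a `response_surface`.
#' @return list with `temp_c` and `duration_weeks`, both grid members.
#' @export
match_constant_condition <- function(mean_temp_c, duration_weeks, surface) {
  nearest_low <- function(grid, x) {
    d <- abs(grid - x)
    grid[which(d <= min(d) + 1e-9)][1]  # grids are sorted: first hit is lowest
  }
  list(temp_c = nearest_low(surface$temps_c, mean_temp_c),
       duration_weeks = nearest_low(surface$durations_weeks, duration_weeks))
}

#' Read field cohort records
#'
#' Expects columns `genotype`, `sow_date`, `transfer_date`, `replicate_id`,
#' `days_to_flower`, `dnf` (0/1).
#' @param path CSV path.
#' @return validated cohort records data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "sow_date", "transfer_date", "days_to_flower", "dnf")
  if (!all(need %in% names(df))) {
    stop_contract("cohort CSV needs columns %s", paste(need, collapse = ", "))
  }
  df$sow_date <- as.Date(df$sow_date)
  df$transfer_date <- as.Date(df$transfer_date)
  df$dnf <- as.logical(df$dnf)
  if (any(df$transfer_date <= df$sow_date)) {
    stop_contract("transfer_date must follow sow_date")
  }
  df
}

#' Predict flowering of one field cohort
#'
#' Implements prediction of field vernalization from cabinet calibration:
#' the cohort's sow-to-transfer interval is summarized by its time-weighted
#' mean temperature and its duration in weeks, then mapped to the response
#' surface either by nearest-cell matching (`mode = "match"`, the
#' constant-condition-matching procedure) or by bilinear interpolation
#' (`mode = "interpolate"`). The two agree exactly when the interval mean
#' and duration are grid members. A cohort matched to an all-DNF cell is
#' flagged `predicted_dnf`.
#'
#' @param cohort list or one-row data frame with `genotype`, `sow_date`,
#'   `transfer_date`, `observed_dtf` (numeric replicate days-to-flower of
#'   the plants that flowered) and optionally `dnf_count`.
#' @param series a [temperature_series()] covering sow to transfer
#'   (soil-surface records preferred when available).
#' @param surface the cohort genotype's `response_surface`, or a
#'   `response_surface_set` containing it.
#' @param mode `"match"` or `"interpolate"`.
#' @param establishment_days days after sowing excluded from the
#'   vernalizing interval (0 keeps the full sow-to-transfer interval).
#' @return a one-row `field_prediction` data frame.
#' @export
predict_cohort <- function(cohort, series, surface,
                           mode = c("match", "interpolate"),
                           establishment_days = 0) {
  mode <- match.arg(mode)
  if (inherits(surface, "response_surface_set")) {
    if (!cohort$genotype %in% names(surface)) {
      stop_contract("genotype '%s' absent from surface set", cohort$genotype)
    }
    surface <- surface[[cohort$genotype]]
  }
  if (surface$genotype != cohort$genotype) {
    stop_contract("surface is for genotype '%s', cohort is '%s'",
                  surface$genotype, cohort$genotype)
  }
  sow <- as.Date(cohort$sow_date)
  transfer <- as.Date(cohort$transfer_date)
  start <- as.POSIXct(paste(sow + establishment_days, "00:00:00"), tz = "UTC")
  end <- as.POSIXct(paste(transfer, "00:00:00"), tz = "UTC")
  tm <- interval_mean_temperature(series, start, end)
  dur_w <- as.numeric(transfer - (sow + establishment_days)) / 7
  if (mode == "match") {
    cell <- match_constant_condition(tm, dur_w, surface)
    i <- match(cell$temp_c, surface$temps_c)
    j <- match(cell$duration_weeks, surface$durations_weeks)
    pred <- surface$mean_dtf[i, j]
    prop_dnf <- surface$prop_dnf[i, j]
    n_cell <- surface$n[i, j]
    sem <- surface$sd_dtf[i, j] / sqrt(max(1, n_cell * (1 - prop_dnf)))
    mt <- cell$temp_c; md <- cell$duration_weeks
  } else {
    q <- interpolate_dtf(surface, tm, dur_w)
    pred <- q$mean_dtf
    prop_dnf <- q$dnf_risk
    sem <- NA_real_
    mt <- NA_real_; md <- NA_real_
  }
  predicted_dnf <- is.na(pred) || (!is.na(prop_dnf) && prop_dnf >= 1)
  obs <- cohort$observed_dtf
  obs_mean <- if (length(obs)) mean(obs) else NA_real_
  out <- data.frame(
    genotype = cohort$genotype, sow_date = sow, transfer_date = transfer,
    interval_mean_temp_c = as.numeric(tm),
    interval_duration_weeks = dur_w,
    matched_cabinet_temp_c = mt, matched_cabinet_duration_weeks = md,
    predicted_dtf = as.numeric(pred), predicted_dnf = predicted_dnf,
    predicted_dnf_risk = as.numeric(prop_dnf),
    matched_cell_sem = as.numeric(sem),
    observed_mean_dtf = obs_mean,
    observed_n = length(obs) + (cohort$dnf_count %||% 0),
    observed_dnf_count = cohort$dnf_count %||% 0,
    residual = obs_mean - as.numeric(pred))
  class(out) <- c("field_prediction", "data.frame")
  out
}

#' Predict all cohorts in a replicate-level cohort table
#'
#' Groups replicate rows by (genotype, sow date, transfer date) and applies
#' [predict_cohort()] to each cohort. Predictions are a pure function of the
#' inputs and independent of row order.
#'
#' @param cohorts replicate records (see [read_cohort_csv()]).
#' @param series a [temperature_series()].
#' @param surface a `response_surface` or `response_surface_set`.
#' @inheritParams predict_cohort
#' @return a `field_prediction` data frame, one row per cohort.
#' @export
predict_cohorts <- function(cohorts, series, surface,
                            mode = c("match", "interpolate"),
                            establishment_days = 0) {
  mode <- match.arg(mode)
  key <- interaction(cohorts$genotype, cohorts$sow_date,
                     cohorts$transfer_date, drop = TRUE)
  rows <- lapply(split(cohorts, key), function(g) {
    predict_cohort(list(genotype = g$genotype[1],
                        sow_date = g$sow_date[1],
                        transfer_date = g$transfer_date[1],
                        observed_dtf = g$days_to_flower[!g$dnf],
                        dnf_count = sum(g$dnf)),
                   series, surface, mode = mode,
                   establishment_days = establishment_days)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype, out$sow_date, out$transfer_date), ]
  rownames(out) <- NULL
  out
}

#' Summarize field-prediction accuracy
#'
#' Per-genotype and pooled residual bias and mean absolute error, plus a
#' 2x2 concordance table of predicted vs observed DNF-majority cohorts.
#'
#' @param predictions a `field_prediction` data frame.
#' @return a `prediction_report` list with `per_genotype`, `pooled`,
#'   `dnf_table`.
#' @export
evaluate_predictions <- function(predictions) {
  if (nrow(predictions) == 0L) stop_contract("need >= 1 prediction")
  per <- function(r) {
    data.frame(n = nrow(r),
               bias = mean(r$residual, na.rm = TRUE),
               mae = mean(abs(r$residual), na.rm = TRUE))
  }
  per_g <- do.call(rbind, lapply(split(predictions, predictions$genotype), per))
  per_g <- cbind(genotype = rownames(per_g), per_g)
  rownames(per_g) <- NULL
  obs_dnf <- predictions$observed_dnf_count > predictions$observed_n / 2
  tab <- table(predicted_dnf = factor(predictions$predicted_dnf,
                                      levels = c(FALSE, TRUE)),
               observed_dnf = factor(obs_dnf, levels = c(FALSE, TRUE)))
  structure(list(per_genotype = per_g,
                 pooled = per(predictions),
                 dnf_table = tab),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>\n  pooled: ")
  cat(sprintf("n %d, bias %.2f d, MAE %.2f d\n",
              x$pooled$n, x$pooled$bias, x$pooled$mae))
  print(x$per_genotype)
  cat("  DNF concordance:\n")
  print(x$dnf_table)
  invisible(x)
}
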