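# shared fixture builders -- everything is generated in code, no data files

hourly_stamps <- function(days, start = "2011-09-01") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  seq(t0, by = 3600, length.out = days * 24)
}

# constant-temperature hourly series
const_series <- function(temp_c, days, start = "2011-09-01") {
  temperature_series(hourly_stamps(days, start), rep(temp_c, days * 24),
                     cadence = "hourly")
}

# hourly series from an explicit temperature vector
hourly_series <- function(temps, start = "2011-09-01") {
  stopifnot(length(temps) %% 24 == 0)
  temperature_series(hourly_stamps(length(temps) / 24, start), temps,
                     cadence = "hourly")
}

# daily_means-shaped frame from explicit daily means (all complete)
dailies_from <- function(means, start = "2011-09-01") {
  data.frame(date = seq(as.Date(start), by = 1, length.out = length(means)),
             daily_mean_c = means,
             n_readings = 24L,
             complete = TRUE)
}

# noiseless flowering records with one replicate per cell at exact means:
# temps x durations grids with a matrix of cell means (temps in rows)
records_from_means <- function(genotype, temps, durations, means,
                               n_reps = 1) {
  grid <- expand.grid(i = seq_along(temps), j = seq_along(durations))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    data.frame(genotype = genotype,
               temp_c = temps[grid$i[k]],
               duration_weeks = durations[grid$j[k]],
               replicate_id = seq_len(n_reps),
               days_to_flower = rep(means[grid$i[k], grid$j[k]], n_reps),
               dnf = FALSE)
  }))
}

write_temp_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
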