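test_that("read_temperature_csv parses, sorts, collapses duplicates, rejects junk", {
  p <- write_temp_csv(data.frame(
    timestamp = c("2011-08-01T00:00:00", "2011-08-01T07:30:00",
                  "2011-08-01T03:15:00"),
    temp_c = c(5, 7, 6)))
  s <- read_temperature_csv(p)
  expect_s3_class(s, "temperature_series")
  expect_equal(nrow(s), 3)
  expect_equal(s$temp_c, c(5, 6, 7))  # re-sorted by time
  expect_identical(attr(s, "cadence"), "irregular")

  pdup <- write_temp_csv(data.frame(
    timestamp = c("2011-08-01T00:00:00", "2011-08-01T00:00:00",
                  "2011-08-01T01:00:00"),
    temp_c = c(5, 7, 6)))
  expect_warning(sdup <- read_temperature_csv(pdup), "duplicate")
  expect_equal(sdup$temp_c, c(6, 6))

  pempty <- write_temp_csv(data.frame(timestamp = character(),
                                      temp_c = numeric()))
  expect_error(read_temperature_csv(pempty), "empty")

  pbad <- write_temp_csv(data.frame(timestamp = c("2011-08-01T00:00:00",
                                                  "not-a-time"),
                                    temp_c = c(5, 6)))
  expect_error(read_temperature_csv(pbad), "row 2")
})

test_that("temperature CSV round-trips bit-identically at printed precision", {
  cfg <- weather_config(season_end = "2011-08-10", seed = 5)
  s <- generate_weather(cfg)
  p <- tempfile(fileext = ".csv")
  write_temperature_csv(s, p, digits = 3)
  s2 <- read_temperature_csv(p)
  p2 <- tempfile(fileext = ".csv")
  write_temperature_csv(s2, p2, digits = 3)
  expect_identical(readLines(p), readLines(p2))
  expect_identical(s$timestamp, s2$timestamp)
  expect_equal(s2$temp_c, round(s$temp_c, 3), tolerance = 1e-12)
})

test_that("synthetic full-autumn trace has one reading per hour and is detected hourly", {
  s <- generate_weather(weather_config(seed = 2))
  expect_equal(nrow(s), 122 * 24)  # 1 Aug - 30 Nov = 122 days
  p <- write_temp_csv(data.frame(
    timestamp = format(s$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temp_c = s$temp_c))
  expect_identical(attr(read_temperature_csv(p), "cadence"), "hourly")
})

test_that("daily_means: thrice-daily policy uses 0600/1200/1800 and flags gaps", {
  ts <- as.POSIXct(paste("2011-09-01", c("06:00", "12:00", "18:00")), tz = "UTC")
  s <- temperature_series(ts, c(2, 8, 5), cadence = "thrice_daily")
  d <- daily_means(s, policy = "thrice_daily")
  expect_equal(d$daily_mean_c, 5)
  expect_true(d$complete)

  s2 <- temperature_series(ts[1:2], c(2, 8), cadence = "irregular")
  d2 <- daily_means(s2, policy = "thrice_daily")
  expect_false(d2$complete)
  expect_equal(d2$n_readings, 2L)
})

test_that("daily_means: hourly policy is exact on constants, interpolates short gaps", {
  s <- const_series(8, 3)
  d <- daily_means(s, policy = "hourly")
  expect_equal(d$daily_mean_c, rep(8, 3))
  expect_true(all(d$complete))

  # drop a 4-hour mid-day gap: linearly interpolated, day stays complete and
  # the mean of a linear ramp is unchanged
  temps <- seq(0, by = 0.5, length.out = 48)
  s3 <- hourly_series(temps)
  keep <- setdiff(seq_len(48), 10:13)
  s3g <- temperature_series(s3$timestamp[keep], s3$temp_c[keep],
                            cadence = "irregular")
  d3 <- daily_means(s3g, policy = "hourly")
  expect_true(all(d3$complete))
  expect_equal(d3$daily_mean_c, daily_means(s3, policy = "hourly")$daily_mean_c,
               tolerance = 1e-12)

  # an 8-hour gap exceeds the interpolation bound: < 20 h covered -> incomplete
  keep2 <- setdiff(seq_len(48), 9:16)
  s4 <- temperature_series(s3$timestamp[keep2], s3$temp_c[keep2],
                           cadence = "irregular")
  d4 <- daily_means(s4, policy = "hourly")
  expect_false(d4$complete[1])
  expect_true(d4$complete[2])
})

test_that("autumn_summary: strict window membership and brute-force fraction", {
  d <- dailies_from(c(-1, 5, 14, 16))
  s <- autumn_summary(d, window = vernalization_window(0, 15, "daily_mean"))
  expect_equal(s$fraction_days_in_window, 0.5)

  d20 <- dailies_from(rep(20, 10))
  expect_equal(autumn_summary(d20)$fraction_days_in_window, 0)

  # boundary values are outside (strict at both bounds)
  db <- dailies_from(c(0, 15, 7))
  expect_equal(autumn_summary(db)$fraction_days_in_window, 1 / 3)

  # oracle equivalence on a random instance (season filter applied by hand)
  set.seed(42)
  vals <- stats::rnorm(300, 8, 6)
  dr <- dailies_from(vals, start = "2011-08-01")
  md <- format(dr$date, "%m-%d")
  vin <- dr$daily_mean_c[md >= "08-01" & md <= "11-30"]
  s2 <- autumn_summary(dr)
  expect_equal(s2$fraction_days_in_window, sum(vin > 0 & vin < 15) / length(vin))
  expect_equal(s2$mean_of_daily_means_c, mean(vin))

  dinc <- dailies_from(c(5, 6))
  dinc$complete <- FALSE
  expect_error(autumn_summary(dinc), "no complete days")
})

test_that("autumn_summary recovers a configured seasonal climatology", {
  # season configured with an 8.86 C mean climatology (15.52 -> 2.2 trend)
  cfg <- weather_config(mean_start_c = 15.52, mean_end_c = 2.2,
                        noise_sd_c = 2.5, seed = 1)
  s <- autumn_summary(daily_means(generate_weather(cfg)))
  expect_lt(abs(s$mean_of_daily_means_c - 8.86), 0.5)
})

test_that("detect_snow_cover finds the clamped span and respects the depth shortcut", {
  expect_equal(nrow(detect_snow_cover(const_series(8, 10))), 0)

  cfg <- weather_config(season_start = "2011-11-01", season_end = "2012-04-20",
                        mean_start_c = 2, mean_end_c = 2,
                        snow_onset_date = "2011-11-15", seed = 7)
  s <- generate_weather(cfg)
  iv <- detect_snow_cover(s)
  expect_equal(nrow(iv), 1)
  clamp_start <- as.POSIXct("2011-11-15 00:00:00", tz = "UTC")
  clamp_end <- s$timestamp[nrow(s)]
  clamped_h <- as.numeric(clamp_end - clamp_start, units = "hours")
  overlap_h <- as.numeric(min(iv$end, clamp_end) - max(iv$start, clamp_start),
                          units = "hours")
  expect_gte(overlap_h / clamped_h, 0.95)

  # depth column wins over the temperature signature
  sd0 <- temperature_series(hourly_stamps(5), rep(8, 120),
                            snow_depth_cm = rep(3, 120), cadence = "hourly")
  ivd <- detect_snow_cover(sd0)
  expect_equal(nrow(ivd), 1)
  expect_identical(ivd$start, sd0$timestamp[1])
  expect_identical(ivd$end, sd0$timestamp[120])
})

test_that("detect_snow_cover intervals are sorted, disjoint and long enough", {
  for (seed in 1:5) {
    cfg <- weather_config(season_start = "2011-10-01", season_end = "2012-02-28",
                          mean_start_c = 4, mean_end_c = -2,
                          snow_onset_date = "2011-12-01", seed = seed)
    iv <- detect_snow_cover(generate_weather(cfg))
    if (nrow(iv) == 0) next
    expect_true(all(diff(as.numeric(iv$start)) > 0))
    if (nrow(iv) > 1) {
      expect_true(all(as.numeric(iv$start[-1]) > as.numeric(iv$end[-nrow(iv)])))
    }
    expect_true(all(as.numeric(iv$end - iv$start, units = "hours") >= 72))
  }
})
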