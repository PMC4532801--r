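#' Configure a synthetic autumn weather trace
#'
#' Parameters of the hourly synthetic weather model: a linear seasonal trend
#' from `mean_start_c` to `mean_end_c` across the season, a sinusoidal
#' diurnal cycle peaking mid-afternoon, stationary AR(1) noise at 1-h lag
#' (autocorrelated, so daily means retain realistic variance), and an
#' optional snow-onset date after which the trace is clamped to
#' `snow_clamp_c` plus a small jitter -- the low-variance near-zero
#' signature of an insulated soil surface. Defaults emulate a northern
#' Scandinavian autumn (1 Aug -- 30 Nov, seasonal mean falling 14 to 0
#' degrees C, i.e. a season average near 7--8 degrees C).
#'
#' @param season_start,season_end Dates (or `"YYYY-MM-DD"`).
#' @param mean_start_c,mean_end_c seasonal trend endpoints, degrees C.
#' @param diurnal_amplitude_c amplitude of the diurnal sinusoid, degrees C.
#' @param noise_sd_c marginal SD of the AR(1) noise, degrees C.
#' @param noise_autocorr AR(1) coefficient at 1 h, in \[0, 1).
#' @param snow_onset_date optional Date; readings on/after it are clamped.
#' @param snow_clamp_c,snow_clamp_jitter_c clamp level and uniform jitter
#'   half-width, degrees C.
#' @param seed integer RNG seed; generation is a pure function of
#'   (config, seed).
#' @param site_label label stored on the generated series.
#' @return a `weather_config` list.
#' @export
weather_config <- function(season_start = "2011-08-01",
                           season_end = "2011-11-30",
                           mean_start_c = 14, mean_end_c = 0,
                           diurnal_amplitude_c = 3,
                           noise_sd_c = 2.5, noise_autocorr = 0.8,
                           snow_onset_date = NULL,
                           snow_clamp_c = 0, snow_clamp_jitter_c = 0.2,
                           seed = 1L, site_label = "synthetic") {
  season_start <- as.Date(season_start)
  season_end <- as.Date(season_end)
  if (season_start >= season_end) stop_contract("season_start must precede season_end")
  if (noise_autocorr < 0 || noise_autocorr >= 1) {
    stop_contract("noise_autocorr must be in [0, 1)")
  }
  if (noise_sd_c < 0) stop_contract("noise_sd_c must be >= 0")
  structure(list(season_start = season_start, season_end = season_end,
                 mean_start_c = mean_start_c, mean_end_c = mean_end_c,
                 diurnal_amplitude_c = diurnal_amplitude_c,
                 noise_sd_c = noise_sd_c, noise_autocorr = noise_autocorr,
                 snow_onset_date = if (is.null(snow_onset_date)) NULL
                                   else as.Date(snow_onset_date),
                 snow_clamp_c = snow_clamp_c,
                 snow_clamp_jitter_c = snow_clamp_jitter_c,
                 seed = as.integer(seed), site_label = site_label),
            class = "weather_config")
}

#' Generate a synthetic hourly weather trace
#'
#' @param config a [weather_config()].
#' @return an hourly [temperature_series()] covering every hour from 00:00 on
#'   the season start to 23:00 on the season end.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "weather_config"))
  t0 <- as.POSIXct(paste(config$season_start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$season_end, "23:00:00"), tz = "UTC")
  ts <- seq(t0, t1, by = 3600)
  n <- length(ts)
  frac <- (seq_len(n) - 1) / (n - 1)
  trend <- config$mean_start_c + (config$mean_end_c - config$mean_start_c) * frac
  hour <- as.integer(format(ts, "%H", tz = "UTC"))
  diurnal <- config$diurnal_amplitude_c * sin(2 * pi * (hour - 9) / 24)
  temps <- with_seed(config$seed, {
    phi <- config$noise_autocorr
    sd <- config$noise_sd_c
    noise <- if (sd == 0) rep(0, n) else {
      # stationary AR(1): marginal SD = sd at every lag-0
      e0 <- stats::rnorm(1, 0, sd)
      innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
      c(e0, as.numeric(stats::filter(innov, phi, method = "recursive",
                                     init = e0)))
    }
    x <- trend + diurnal + noise
    if (!is.null(config$snow_onset_date)) {
      snow <- as.Date(ts, tz = "UTC") >= config$snow_onset_date
      x[snow] <- config$snow_clamp_c +
        stats::runif(sum(snow), -config$snow_clamp_jitter_c,
                     config$snow_clamp_jitter_c)
    }
    x
  })
  temperature_series(ts, temps, cadence = "hourly",
                     site_label = config$site_label)
}

#' Parametric ground-truth flowering response for a synthetic genotype
#'
#' The synthetic truth combines a Gaussian temperature-effectiveness kernel
#' with hard support and a Hill-type duration response:
#' `K(T) = exp(-(T - t_opt)^2 / (2 kernel_sd^2))` for
#' `t_min < T < t_max`, else 0; vernalization progress
#' `P = (d K)^h / ((d K)^h + full_weeks^h)`; mean days-to-flower
#' `nv_dtf - (nv_dtf - sat_dtf) P`. The sharp support gives a hard
#' effective range and the Gaussian shape a smooth optimum.
#'
#' @param genotype label.
#' @param nv_dtf non-vernalized mean days-to-flower.
#' @param sat_dtf fully vernalized mean days-to-flower (`< nv_dtf`).
#' @param t_opt_c optimal vernalizing temperature, degrees C.
#' @param kernel_sd_c Gaussian kernel SD, degrees C.
#' @param t_min_c,t_max_c hard support bounds (`t_min < t_opt < t_max`).
#' @param full_weeks Hill half-saturation duration at the optimum, weeks.
#' @param hill_h Hill shape exponent.
#' @param rep_noise_sd replicate noise SD, days.
#' @param dnf_threshold_dtf latent days-to-flower above which a replicate is
#'   recorded DNF at this censoring bound (the end of scoring).
#' @return a `genotype_params` list.
#' @export
genotype_params <- function(genotype, nv_dtf, sat_dtf, t_opt_c, kernel_sd_c,
                            t_min_c = 0, t_max_c = 15, full_weeks,
                            hill_h = 2, rep_noise_sd = 0.1 * (nv_dtf - sat_dtf),
                            dnf_threshold_dtf = nv_dtf + 4 * rep_noise_sd) {
  if (sat_dtf >= nv_dtf) stop_contract("sat_dtf must be < nv_dtf")
  if (!(t_min_c < t_opt_c && t_opt_c < t_max_c)) {
    stop_contract("need t_min_c < t_opt_c < t_max_c")
  }
  if (full_weeks <= 0) stop_contract("full_weeks must be > 0")
  structure(list(genotype = genotype, nv_dtf = nv_dtf, sat_dtf = sat_dtf,
                 t_opt_c = t_opt_c, kernel_sd_c = kernel_sd_c,
                 t_min_c = t_min_c, t_max_c = t_max_c,
                 full_weeks = full_weeks, hill_h = hill_h,
                 rep_noise_sd = rep_noise_sd,
                 dnf_threshold_dtf = dnf_threshold_dtf),
            class = "genotype_params")
}

#' Ground-truth mean days-to-flower
#'
#' @param params a [genotype_params()].
#' @param temp_c,duration_weeks numeric vectors (recycled).
#' @return mean days-to-flower under the synthetic truth.
#' @export
true_dtf <- function(params, temp_c, duration_weeks) {
  n <- max(length(temp_c), length(duration_weeks))
  temp_c <- rep_len(temp_c, n)
  d <- rep_len(duration_weeks, n)
  K <- exp(-(temp_c - params$t_opt_c)^2 / (2 * params$kernel_sd_c^2))
  K[temp_c <= params$t_min_c | temp_c >= params$t_max_c] <- 0
  dk <- (d * K)^params$hill_h
  P <- dk / (dk + params$full_weeks^params$hill_h)
  params$nv_dtf - (params$nv_dtf - params$sat_dtf) * P
}

#' Synthetic genotype presets
#'
#' Five synthetic profiles qualitatively emulating the contrast between a
#' late, sharply 8-degree-optimal northern Swedish accession, a southern
#' Swedish accession with a similar but milder optimum, and three lines that
#' vernalize nearly equally well across 2--8 degrees C. Parameters are
#' invented ground truth for testing -- they are labelled synthetic and are
#' not measurements. Replicate noise is 10% of each genotype's maximal
#' flowering-time reduction.
#'
#' @return named list of [genotype_params()].
#' @export
genotype_presets <- function() {
  list(
    col_fri_like = genotype_params("col_fri_like", nv_dtf = 140, sat_dtf = 40,
                                   t_opt_c = 5, kernel_sd_c = 4.5,
                                   full_weeks = 6),
    edi0_like = genotype_params("edi0_like", nv_dtf = 130, sat_dtf = 38,
                                t_opt_c = 5, kernel_sd_c = 4.5,
                                full_weeks = 6),
    ull25_like = genotype_params("ull25_like", nv_dtf = 145, sat_dtf = 42,
                                 t_opt_c = 5, kernel_sd_c = 4.5,
                                 full_weeks = 12),
    var26_like = genotype_params("var26_like", nv_dtf = 140, sat_dtf = 40,
                                 t_opt_c = 7.5, kernel_sd_c = 3.5,
                                 full_weeks = 8),
    lov1_like = genotype_params("lov1_like", nv_dtf = 150, sat_dtf = 40,
                                t_opt_c = 8, kernel_sd_c = 3.5,
                                full_weeks = 12)
  )
}

#' Default cabinet design grid
#'
#' Seven constant temperatures and four durations (weeks, 0 = the
#' non-vernalized control).
#' @return list with `temps_c` and `durations_weeks`.
#' @export
cabinet_design <- function() {
  list(temps_c = c(0, 2, 5, 8, 10, 12, 14),
       durations_weeks = c(0, 4, 6, 12))
}

#' Generate synthetic cabinet flowering records
#'
#' Per replicate, days-to-flower is the genotype truth plus Gaussian noise;
#' latent values above the DNF threshold are recorded as DNF at the
#' threshold (censoring bound). Reproducible per seed.
#'
#' @param params_list a [genotype_params()] or list of them.
#' @param temps_c,durations_weeks design grid (defaults: [cabinet_design()]).
#' @param n_reps replicates per cell.
#' @param seed integer seed.
#' @return flowering records data frame (see [read_flowering_csv()]).
#' @export
generate_flowering <- function(params_list,
                               temps_c = cabinet_design()$temps_c,
                               durations_weeks = cabinet_design()$durations_weeks,
                               n_reps = 10, seed = 1L) {
  if (inherits(params_list, "genotype_params")) params_list <- list(params_list)
  if (n_reps < 1) stop_contract("n_reps must be >= 1")
  grid <- expand.grid(temp_c = temps_c, duration_weeks = durations_weeks,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    out <- lapply(params_list, function(p) {
      mu <- true_dtf(p, grid$temp_c, grid$duration_weeks)
      reps <- lapply(seq_len(nrow(grid)), function(i) {
        latent <- mu[i] + stats::rnorm(n_reps, 0, p$rep_noise_sd)
        dnf <- latent > p$dnf_threshold_dtf
        data.frame(genotype = p$genotype,
                   temp_c = grid$temp_c[i],
                   duration_weeks = grid$duration_weeks[i],
                   replicate_id = seq_len(n_reps),
                   days_to_flower = pmax(1, ifelse(dnf, p$dnf_threshold_dtf,
                                                   latent)),
                   dnf = dnf)
      })
      do.call(rbind, reps)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic field transplant experiment
#'
#' Generates an autumn weather trace and cohort flowering records whose
#' truth is `true_dtf` evaluated at each cohort's (interval mean
#' temperature, interval duration in weeks) -- the self-consistency that
#' makes field prediction by constant-temperature matching recoverable.
#'
#' @param config a [weather_config()] (its seed drives the weather).
#' @param params_list a [genotype_params()] or list of them.
#' @param sow_date Date the cohorts are established in the field.
#' @param transfer_dates Dates of transfer to warm conditions (within the
#'   weather span).
#' @param n_reps replicates per cohort.
#' @param seed integer seed for the flowering noise.
#' @return list with `series` (the weather trace) and `cohorts` (replicate
#'   records: `genotype`, `sow_date`, `transfer_date`, `replicate_id`,
#'   `days_to_flower`, `dnf`).
#' @export
generate_field_experiment <- function(config, params_list, sow_date,
                                      transfer_dates, n_reps = 12,
                                      seed = 1L) {
  if (inherits(params_list, "genotype_params")) params_list <- list(params_list)
  sow_date <- as.Date(sow_date)
  transfer_dates <- as.Date(transfer_dates)
  if (any(transfer_dates <= sow_date)) {
    stop_contract("transfer dates must follow the sow date")
  }
  if (any(transfer_dates > config$season_end)) {
    stop_contract("transfer dates must lie within the weather span")
  }
  series <- generate_weather(config)
  cohorts <- with_seed(seed, {
    rows <- list()
    for (td in seq_along(transfer_dates)) {
      start <- as.POSIXct(paste(sow_date, "00:00:00"), tz = "UTC")
      end <- as.POSIXct(paste(transfer_dates[td], "00:00:00"), tz = "UTC")
      tm <- interval_mean_temperature(series, start, end)
      wk <- as.numeric(transfer_dates[td] - sow_date) / 7
      for (p in params_list) {
        mu <- true_dtf(p, tm, wk)
        latent <- mu + stats::rnorm(n_reps, 0, p$rep_noise_sd)
        dnf <- latent > p$dnf_threshold_dtf
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = p$genotype, sow_date = sow_date,
          transfer_date = transfer_dates[td],
          replicate_id = seq_len(n_reps),
          days_to_flower = pmax(1, ifelse(dnf, p$dnf_threshold_dtf, latent)),
          dnf = dnf)
      }
    }
    do.call(rbind, rows)
  })
  rownames(cohorts) <- NULL
  list(series = series, cohorts = cohorts)
}
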