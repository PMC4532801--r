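test_that("fit_surface summarizes cells and handles DNF censoring", {
  rec <- data.frame(genotype = "g", temp_c = 8, duration_weeks = 6,
                    replicate_id = 1:10, days_to_flower = 60, dnf = FALSE)
  nv <- data.frame(genotype = "g", temp_c = 8, duration_weeks = 0,
                   replicate_id = 1:10, days_to_flower = 120, dnf = FALSE)
  s <- fit_surface(rbind(rec, nv))
  cell <- s$cells[s$cells$duration_weeks == 6, ]
  expect_equal(cell$mean_dtf, 60)
  expect_equal(cell$sd_dtf, 0)
  expect_equal(cell$prop_dnf, 0)
  expect_equal(s$nv_mean_dtf, 120)

  # 5 of 10 DNF: mean over the 5 flowering, prop_dnf 0.5
  rec2 <- rec
  rec2$dnf <- rep(c(TRUE, FALSE), 5)
  rec2$days_to_flower <- ifelse(rec2$dnf, 180, c(0, 50, 0, 60, 0, 70, 0, 80, 0, 90)[1:10])
  rec2$days_to_flower[rec2$days_to_flower == 0] <- 180
  s2 <- fit_surface(rbind(rec2, nv))
  cell2 <- s2$cells[s2$cells$duration_weeks == 6, ]
  expect_equal(cell2$prop_dnf, 0.5)
  expect_equal(cell2$mean_dtf, mean(c(50, 60, 70, 80, 90)))

  # censored-mean mode includes the bounds
  s3 <- fit_surface(rbind(rec2, nv), censored_mean = TRUE)
  cell3 <- s3$cells[s3$cells$duration_weeks == 6, ]
  expect_equal(cell3$mean_dtf, mean(rec2$days_to_flower))

  expect_error(fit_surface(rec), "non-vernalized")
})

test_that("fitted cells track generator truth on a Fig-1-like design", {
  presets <- genotype_presets()
  rec <- generate_flowering(presets, n_reps = 10, seed = 11)
  surfs <- fit_surface(rec)
  expect_s3_class(surfs, "response_surface_set")
  for (p in presets) {
    s <- surfs[[p$genotype]]
    truth <- outer(s$temps_c, s$durations_weeks,
                   function(t, d) true_dtf(p, t, d))
    sem <- p$rep_noise_sd / sqrt(pmax(1, s$n * (1 - s$prop_dnf)))
    ok <- abs(s$mean_dtf - truth) <= 3 * sem
    # censoring shifts all-flowering cells only negligibly; allow rare misses
    expect_gte(mean(ok, na.rm = TRUE), 0.9)
  }
})

test_that("interpolation is exact at nodes and linear between them", {
  means <- rbind(c(100, 60), c(100, 80))
  rec <- records_from_means("g", temps = c(5, 8), durations = c(0, 6), means)
  s <- fit_surface(rec)
  q <- interpolate_dtf(s, 6.5, 6)
  expect_equal(q$mean_dtf, 70)
  # node identity, all four nodes
  for (i in 1:2) for (j in 1:2) {
    expect_identical(interpolate_dtf(s, c(5, 8)[i], c(0, 6)[j])$mean_dtf,
                     means[i, j])
  }
  expect_warning(qc <- interpolate_dtf(s, 20, 6), "clamped")
  expect_equal(qc$mean_dtf, 80)
  expect_true(qc$clamped)

  rec1 <- records_from_means("g", temps = c(5, 8), durations = 0,
                             matrix(100, 2, 1))
  expect_error(interpolate_dtf(fit_surface(rec1), 6, 0), ">= 2")
})

test_that("interpolation matches an independently coded bilinear oracle", {
  set.seed(19)
  temps <- c(0, 2, 5, 8, 10, 12, 14)
  durs <- c(0, 4, 6, 12)
  means <- matrix(stats::runif(28, 40, 150), 7, 4)
  s <- fit_surface(records_from_means("g", temps, durs, means))
  # oracle: two 1-D linear interpolations (temperature first, then duration)
  oracle <- function(tq, dq) {
    per_dur <- vapply(seq_along(durs), function(j) {
      stats::approx(temps, means[, j], xout = tq)$y
    }, numeric(1))
    stats::approx(durs, per_dur, xout = dq)$y
  }
  for (k in 1:200) {
    tq <- stats::runif(1, 0, 14)
    dq <- stats::runif(1, 0, 12)
    expect_equal(interpolate_dtf(s, tq, dq)$mean_dtf, oracle(tq, dq),
                 tolerance = 1e-9)
  }
})

test_that("refitting on node predictions recovers the cell means", {
  set.seed(23)
  temps <- c(0, 5, 10)
  durs <- c(0, 6, 12)
  means <- matrix(stats::runif(9, 40, 150), 3, 3)
  s <- fit_surface(records_from_means("g", temps, durs, means))
  nodes <- expand.grid(temp_c = temps, duration_weeks = durs)
  pred <- interpolate_dtf(s, nodes$temp_c, nodes$duration_weeks)
  rec2 <- data.frame(genotype = "g", temp_c = nodes$temp_c,
                     duration_weeks = nodes$duration_weeks,
                     replicate_id = 1L, days_to_flower = pred$mean_dtf,
                     dnf = FALSE)
  s2 <- fit_surface(rec2)
  expect_equal(s2$mean_dtf, s$mean_dtf, tolerance = 1e-12)
})

test_that("optimal_temperature: argmin, tie and DNF rules", {
  temps <- c(2, 5, 8)
  flat <- fit_surface(records_from_means("g", temps, c(0, 6),
                                         cbind(rep(120, 3), rep(80, 3))))
  o <- optimal_temperature(flat, 6)
  expect_equal(as.numeric(o), 2)
  expect_true(attr(o, "tie"))

  mono <- fit_surface(records_from_means("g", temps, c(0, 6),
                                         cbind(rep(120, 3), c(100, 90, 80))))
  expect_equal(as.numeric(optimal_temperature(mono, 6)), 8)
  expect_error(optimal_temperature(mono, 5), "not in grid")

  # a DNF-dominated cell cannot win
  rec <- records_from_means("g", temps, c(0, 6),
                            cbind(rep(120, 3), c(100, 90, 60)))
  rec$dnf[rec$temp_c == 8 & rec$duration_weeks == 6] <- TRUE
  s <- fit_surface(rec)
  expect_equal(as.numeric(optimal_temperature(s, 6)), 5)
})

test_that("optimal_temperature recovers a randomized generator optimum", {
  # property: with a sharp kernel, argmin over fitted cells lands on the grid
  # point nearest t_opt. Near the midpoint between two grid temperatures the
  # nearest label is not identifiable at n = 10, so a co-near point (at most
  # 1 C farther) also counts as success.
  grid_t <- cabinet_design()$temps_c
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed * 13 + 1)
    t_opt <- stats::runif(1, 4, 10)
    p <- genotype_params("rand", nv_dtf = 140, sat_dtf = 40, t_opt_c = t_opt,
                         kernel_sd_c = 2.5, full_weeks = 6,
                         dnf_threshold_dtf = 1000)
    rec <- generate_flowering(p, n_reps = 10, seed = seed)
    got <- as.numeric(optimal_temperature(fit_surface(rec), 6))
    if (abs(got - t_opt) <= min(abs(grid_t - t_opt)) + 1.0) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("effective_range interpolates criterion crossings linearly", {
  # relative effect profile 0, 0.6, 1, 0.6, 0 over 0..16 C:
  # half-effect crossings at 10/3 and 38/3 by linear-crossing arithmetic
  temps <- c(0, 4, 8, 12, 16)
  nv <- 120
  eff <- c(0, 0.6, 1, 0.6, 0) * 40
  s <- fit_surface(records_from_means("g", temps, c(0, 6),
                                      cbind(rep(nv, 5), nv - eff)))
  r <- effective_range(s, 6, criterion_fraction = 0.5)
  expect_equal(r$t_low_c, 10 / 3, tolerance = 1e-12)
  expect_equal(r$t_high_c, 38 / 3, tolerance = 1e-12)
  expect_equal(r$t_opt_c, 8)

  # criterion 1 degenerates to the optimum
  r1 <- effective_range(s, 6, criterion_fraction = 1)
  expect_equal(r1$t_low_c, 8)
  expect_equal(r1$t_high_c, 8)

  # when the effect still exceeds the criterion at the grid edge the bound
  # clamps there
  s2 <- fit_surface(records_from_means("g", temps, c(0, 6),
                                       cbind(rep(nv, 5), nv - c(30, 36, 40, 36, 30))))
  r2 <- effective_range(s2, 6, criterion_fraction = 0.5)
  expect_equal(r2$t_low_c, 0)
  expect_equal(r2$t_high_c, 16)

  flat <- fit_surface(records_from_means("g", temps, c(0, 6),
                                         cbind(rep(nv, 5), rep(nv, 5))))
  expect_error(effective_range(flat, 6), "positive vernalization effect")
})

test_that("effective_range recovers the generator-truth half-effect range", {
  # the estimand of the half-maximum criterion is the truth's half-effect
  # span, not the hard kernel support (see the methods vignette)
  p <- genotype_presets()$lov1_like
  truth_rel <- function(t) {
    e <- p$nv_dtf - true_dtf(p, t, 12)
    e / max(p$nv_dtf - true_dtf(p, seq(0, 15, by = 0.01), 12))
  }
  tt <- seq(0, 15, by = 0.001)
  inside <- tt[truth_rel(tt) >= 0.5]
  truth_lo <- min(inside); truth_hi <- max(inside)
  lows <- highs <- numeric(20)
  for (seed in 1:20) {
    s <- fit_surface(generate_flowering(p, n_reps = 10, seed = 100 + seed))
    r <- effective_range(s, 12)
    lows[seed] <- r$t_low_c; highs[seed] <- r$t_high_c
  }
  expect_lt(abs(mean(lows) - truth_lo), 1.0)
  expect_lt(abs(mean(highs) - truth_hi), 1.0)
})

test_that("surface CSV round-trips through write/read", {
  surfs <- fit_surface(generate_flowering(genotype_presets()[1:2], seed = 3))
  p <- tempfile(fileext = ".csv")
  write_surface_csv(surfs, p)
  back <- read_surface_csv(p)
  expect_setequal(names(back), names(surfs))
  g <- names(surfs)[1]
  expect_equal(back[[g]]$mean_dtf, surfs[[g]]$mean_dtf, tolerance = 1e-9)
  expect_equal(back[[g]]$nv_mean_dtf, surfs[[g]]$nv_mean_dtf, tolerance = 1e-9)
})
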