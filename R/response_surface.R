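#' Read a flowering-time CSV
#'
#' Expects columns `genotype`, `temp_c`, `duration_weeks`, `replicate_id`,
#' `days_to_flower`, `dnf` (0/1). For DNF (did-not-flower) replicates
#' `days_to_flower` records the censoring bound (the last day scored).
#'
#' @param path CSV path.
#' @return a validated data frame of flowering records.
#' @export
read_flowering_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_flowering_records(df)
}

validate_flowering_records <- function(records) {
  need <- c("genotype", "temp_c", "duration_weeks", "days_to_flower", "dnf")
  if (!all(need %in% names(records))) {
    stop_contract("flowering records need columns %s", paste(need, collapse = ", "))
  }
  records$dnf <- as.logical(records$dnf)
  if (any(records$duration_weeks < 0)) stop_contract("duration_weeks must be >= 0")
  bad <- !records$dnf & records$days_to_flower <= 0
  if (any(bad)) stop_contract("days_to_flower must be > 0 for flowering replicates")
  records
}

new_response_surface <- function(genotype, cells, nv_mean_dtf) {
  temps <- sort(unique(cells$temp_c))
  durs <- sort(unique(cells$duration_weeks))
  shape <- c(length(temps), length(durs))
  mk <- function(col) {
    m <- matrix(NA_real_, shape[1], shape[2], dimnames = list(temps, durs))
    m[cbind(match(cells$temp_c, temps), match(cells$duration_weeks, durs))] <- cells[[col]]
    m
  }
  structure(list(
    genotype = genotype,
    temps_c = temps,
    durations_weeks = durs,
    cells = cells,
    mean_dtf = mk("mean_dtf"),
    sd_dtf = mk("sd_dtf"),
    n = mk("n"),
    prop_dnf = mk("prop_dnf"),
    nv_mean_dtf = nv_mean_dtf
  ), class = "response_surface")
}

#' Fit flowering-time response surfaces
#'
#' Summarizes replicate flowering records into one cell per (genotype,
#' temperature, duration): mean, SD and n of days-to-flower over the
#' replicates that flowered, plus the proportion that did not flower
#' (`prop_dnf`). DNF replicates are excluded from the mean by default and
#' carried as a censoring proportion; with `censored_mean = TRUE` their
#' censoring bounds are included (treating DNF as "at least this late").
#' Cells where every replicate is DNF get an `NA` mean. A non-vernalized
#' (duration 0) condition must be present per genotype; its pooled mean is
#' stored as `nv_mean_dtf`.
#'
#' @param records flowering records (see [read_flowering_csv()]).
#' @param censored_mean include DNF censoring bounds in cell means.
#' @return a `response_surface` for a single genotype, or a named
#'   `response_surface_set` list when several genotypes are present.
#' @export
fit_surface <- function(records, censored_mean = FALSE) {
  records <- validate_flowering_records(records)
  genos <- unique(records$genotype)
  fit1 <- function(g) {
    r <- records[records$genotype == g, , drop = FALSE]
    if (!any(r$duration_weeks == 0)) {
      stop_contract("genotype '%s' lacks a non-vernalized (duration 0) condition", g)
    }
    key <- interaction(r$temp_c, r$duration_weeks, drop = TRUE)
    cell <- function(idx) {
      ri <- r[idx, , drop = FALSE]
      use <- if (censored_mean) rep(TRUE, nrow(ri)) else !ri$dnf
      data.frame(
        genotype = g,
        temp_c = ri$temp_c[1],
        duration_weeks = ri$duration_weeks[1],
        mean_dtf = if (any(use)) mean(ri$days_to_flower[use]) else NA_real_,
        sd_dtf = if (sum(use) > 1) stats::sd(ri$days_to_flower[use]) else
          if (any(use)) 0 else NA_real_,
        n = nrow(ri),
        prop_dnf = mean(ri$dnf))
    }
    cells <- do.call(rbind, lapply(split(seq_len(nrow(r)), key), cell))
    rownames(cells) <- NULL
    nv <- r[r$duration_weeks == 0, , drop = FALSE]
    nv_use <- if (censored_mean) rep(TRUE, nrow(nv)) else !nv$dnf
    nv_mean <- if (any(nv_use)) mean(nv$days_to_flower[nv_use]) else NA_real_
    new_response_surface(g, cells, nv_mean)
  }
  if (length(genos) == 1L) return(fit1(genos))
  out <- lapply(genos, fit1)
  names(out) <- genos
  structure(out, class = "response_surface_set")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> genotype %s: %d temps x %d durations, NV mean %.1f d\n",
              x$genotype, length(x$temps_c), length(x$durations_weeks),
              x$nv_mean_dtf))
  print(round(x$mean_dtf, 1))
  invisible(x)
}

#' @export
print.response_surface_set <- function(x, ...) {
  cat(sprintf("<response_surface_set> %d genotypes: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Write / read surface cells as CSV
#'
#' One row per cell with the summary fields; a written surface can be read
#' back with [read_surface_csv()].
#'
#' @param surface a `response_surface` or `response_surface_set`.
#' @param path CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  cells <- if (inherits(surface, "response_surface_set")) {
    do.call(rbind, lapply(surface, function(s) s$cells))
  } else {
    surface$cells
  }
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_surface_csv <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  genos <- unique(cells$genotype)
  build <- function(g) {
    cg <- cells[cells$genotype == g, , drop = FALSE]
    nv <- cg[cg$duration_weeks == 0, , drop = FALSE]
    w <- nv$n * (1 - nv$prop_dnf)
    nv_mean <- if (sum(w) > 0) stats::weighted.mean(nv$mean_dtf, w, na.rm = TRUE)
               else NA_real_
    new_response_surface(g, cg, nv_mean)
  }
  if (length(genos) == 1L) return(build(genos))
  out <- lapply(genos, build)
  names(out) <- genos
  structure(out, class = "response_surface_set")
}

#' Bilinear interpolation of a response surface
#'
#' Predicts mean days-to-flower and DNF risk at arbitrary (temperature,
#' duration) queries by bilinear interpolation of the cell means over the
#' grid. Exact at grid nodes. Queries outside the grid's hull are clamped to
#' the nearest edge with a warning. The grid is deliberately interpolated
#' linearly: the duration axis is coarse, and smoother fits would invent
#' curvature the data cannot support.
#'
#' @param surface a `response_surface` with at least 2 temperatures and 2
#'   durations.
#' @param temp_c,duration_weeks numeric query vectors (recycled to common
#'   length).
#' @return data frame with `temp_c`, `duration_weeks`, `mean_dtf`,
#'   `dnf_risk`, `clamped`.
#' @export
interpolate_dtf <- function(surface, temp_c, duration_weeks) {
  if (!inherits(surface, "response_surface")) {
    stop_contract("`surface` must be a response_surface")
  }
  tg <- surface$temps_c
  dg <- surface$durations_weeks
  if (length(tg) < 2L || length(dg) < 2L) {
    stop_contract("interpolation needs >= 2 temperatures and >= 2 durations")
  }
  n <- max(length(temp_c), length(duration_weeks))
  temp_c <- rep_len(temp_c, n)
  duration_weeks <- rep_len(duration_weeks, n)
  clamped <- temp_c < tg[1] | temp_c > tg[length(tg)] |
    duration_weeks < dg[1] | duration_weeks > dg[length(dg)]
  if (any(clamped)) {
    warning(sprintf("%d quer%s outside the grid hull clamped to the edge",
                    sum(clamped), if (sum(clamped) == 1) "y" else "ies"),
            call. = FALSE)
  }
  tq <- pmin(pmax(temp_c, tg[1]), tg[length(tg)])
  dq <- pmin(pmax(duration_weeks, dg[1]), dg[length(dg)])
  bilin <- function(M) {
    i <- findInterval(tq, tg, rightmost.closed = TRUE)
    j <- findInterval(dq, dg, rightmost.closed = TRUE)
    i <- pmin(i, length(tg) - 1L)
    j <- pmin(j, length(dg) - 1L)
    u <- (tq - tg[i]) / (tg[i + 1L] - tg[i])
    v <- (dq - dg[j]) / (dg[j + 1L] - dg[j])
    (1 - u) * (1 - v) * M[cbind(i, j)] +
      u * (1 - v) * M[cbind(i + 1L, j)] +
      (1 - u) * v * M[cbind(i, j + 1L)] +
      u * v * M[cbind(i + 1L, j + 1L)]
  }
  data.frame(temp_c = temp_c, duration_weeks = duration_weeks,
             mean_dtf = bilin(surface$mean_dtf),
             dnf_risk = bilin(surface$prop_dnf),
             clamped = clamped)
}

#' Most effective vernalization temperature at a given duration
#'
#' The grid temperature minimizing mean days-to-flower at the given
#' duration. Cells dominated by DNF (`prop_dnf > dnf_max`) or with no
#' flowering replicates are excluded. Exact ties go to the lower
#' temperature and are reported via the `tie` attribute.
#'
#' @param surface a `response_surface`.
#' @param duration_weeks a duration present in the grid.
#' @param dnf_max maximum DNF proportion for a cell to be considered.
#' @return the optimal temperature (scalar, attributes `mean_dtf`, `tie`).
#' @export
optimal_temperature <- function(surface, duration_weeks, dnf_max = 0.5) {
  j <- match(duration_weeks, surface$durations_weeks)
  if (is.na(j)) {
    stop_contract("duration %g weeks not in grid (%s)", duration_weeks,
                  paste(surface$durations_weeks, collapse = ", "))
  }
  m <- surface$mean_dtf[, j]
  p <- surface$prop_dnf[, j]
  ok <- !is.na(m) & !is.na(p) & p <= dnf_max
  if (!any(ok)) stop_contract("all cells at duration %g are DNF-dominated", duration_weeks)
  m[!ok] <- Inf
  best <- min(m)
  hits <- which(m == best)
  structure(surface$temps_c[hits[1]],
            mean_dtf = best,
            tie = length(hits) > 1L)
}

#' Effective temperature range for vernalization
#'
#' The contiguous temperature span around the optimum within which the
#' vernalization effect -- the reduction in mean days-to-flower relative to
#' the non-vernalized control, scaled by the maximal reduction across
#' temperatures -- exceeds `criterion_fraction`. Crossings between grid
#' temperatures are linearly interpolated; when the effect still exceeds the
#' criterion at a grid edge the bound is reported at that edge. The
#' half-maximal default mirrors the usual dose-response convention; the
#' criterion is an exposed parameter because no formula is standard.
#'
#' @param surface a `response_surface` with an NV mean and >= 3 grid
#'   temperatures.
#' @param duration_weeks a duration present in the grid.
#' @param criterion_fraction fraction of the maximal flowering-time
#'   reduction (0--1].
#' @return an `effective_range` list: `genotype`, `t_low_c`, `t_high_c`,
#'   `t_opt_c`, `criterion_fraction`, `duration_weeks_used`, `max_effect_days`.
#' @export
effective_range <- function(surface, duration_weeks, criterion_fraction = 0.5) {
  if (is.na(surface$nv_mean_dtf)) stop_contract("surface has no NV mean")
  if (criterion_fraction <= 0 || criterion_fraction > 1) {
    stop_contract("criterion_fraction must be in (0, 1]")
  }
  j <- match(duration_weeks, surface$durations_weeks)
  if (is.na(j)) stop_contract("duration %g weeks not in grid", duration_weeks)
  m <- unname(surface$mean_dtf[, j])
  keep <- !is.na(m)
  temps <- unname(surface$temps_c[keep])
  if (length(temps) < 3L) stop_contract("need >= 3 grid temperatures with estimates")
  effect <- surface$nv_mean_dtf - m[keep]
  if (max(effect) <= 0) stop_contract("no cell shows a positive vernalization effect")
  rel <- effect / max(effect)
  opt <- which.max(rel)
  crossing <- function(i_out, i_in) {
    # linear crossing of `criterion_fraction` between an outside and an
    # inside grid point
    temps[i_out] + (temps[i_in] - temps[i_out]) *
      (criterion_fraction - rel[i_out]) / (rel[i_in] - rel[i_out])
  }
  i <- opt
  while (i > 1L && rel[i - 1L] >= criterion_fraction) i <- i - 1L
  t_low <- if (i == 1L) temps[1] else crossing(i - 1L, i)
  i <- opt
  while (i < length(temps) && rel[i + 1L] >= criterion_fraction) i <- i + 1L
  t_high <- if (i == length(temps)) temps[length(temps)] else crossing(i + 1L, i)
  structure(list(genotype = surface$genotype,
                 t_low_c = t_low, t_high_c = t_high,
                 t_opt_c = temps[opt],
                 criterion_fraction = criterion_fraction,
                 duration_weeks_used = duration_weeks,
                 max_effect_days = max(effect)),
            class = "effective_range")
}

#' @export
print.effective_range <- function(x, ...) {
  cat(sprintf("<effective_range> %s: (%.2f, %.2f) C at >=%g of max effect (%.1f d), %g wk\n",
              x$genotype, x$t_low_c, x$t_high_c, x$criterion_fraction,
              x$max_effect_days, x$duration_weeks_used))
  invisible(x)
}
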