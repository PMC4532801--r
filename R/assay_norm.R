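#' Reference-gene normalized expression
#'
#' Relative target abundance divided by the reference-gene (e.g. UBC)
#' abundance from the same sample. Inputs are post-standard-curve relative
#' quantities, not raw Ct values. Downstream statistics should operate on
#' the log of these ratios. The ratio is homogeneous of degree zero: jointly
#' rescaling both quantities leaves it unchanged.
#'
#' @param target_quantity,reference_quantity strictly positive numeric
#'   vectors (recycled).
#' @return target / reference ratios.
#' @export
normalized_expression <- function(target_quantity, reference_quantity) {
  if (any(target_quantity <= 0) || any(reference_quantity <= 0)) {
    stop_contract("quantities must be strictly positive")
  }
  target_quantity / reference_quantity
}

#' ChIP double-ratio normalization
#'
#' Histone-mark enrichment at the assayed locus normalized first to total
#' H3 and then to the same mark/H3 ratio at an internal control locus:
#' `(k27_flc / h3_flc) / (k27_stm / h3_stm)`. Invariant under independent
#' common rescaling of the (k27_flc, h3_flc) pair and of the
#' (k27_stm, h3_stm) pair.
#'
#' @param k27_flc,h3_flc,k27_stm,h3_stm strictly positive relative
#'   recoveries (vectors recycled).
#' @return double ratios.
#' @export
chip_double_ratio <- function(k27_flc, h3_flc, k27_stm, h3_stm) {
  vals <- list(k27_flc, h3_flc, k27_stm, h3_stm)
  if (any(vapply(vals, function(v) any(v <= 0), logical(1)))) {
    stop_contract("all recoveries must be strictly positive")
  }
  (k27_flc / h3_flc) / (k27_stm / h3_stm)
}

#' Paired comparison of ChIP profiles across primer pairs
#'
#' Pairs two conditions by primer pair, computes the per-pair difference of
#' double ratios, and summarizes with the Wilcoxon signed-rank statistic
#' (the pairing-by-primer-pair construction is the bespoke part; the test
#' itself is the standard routine).
#'
#' @param cond_a,cond_b data frames with columns `primer_pair`, `k27_flc`,
#'   `h3_flc`, `k27_stm`, `h3_stm`, covering the same primer-pair set.
#' @return a `profile_comparison` list: `differences` (per-pair data
#'   frame), `statistic` (signed-rank V, sum of ranks of positive
#'   differences), `p_value`, `direction`.
#' @export
profile_comparison <- function(cond_a, cond_b) {
  need <- c("primer_pair", "k27_flc", "h3_flc", "k27_stm", "h3_stm")
  for (d in list(cond_a, cond_b)) {
    if (!all(need %in% names(d))) {
      stop_contract("profiles need columns %s", paste(need, collapse = ", "))
    }
  }
  if (!setequal(cond_a$primer_pair, cond_b$primer_pair) ||
      anyDuplicated(cond_a$primer_pair) || anyDuplicated(cond_b$primer_pair)) {
    stop_contract("conditions must cover the same primer-pair set exactly once")
  }
  cond_b <- cond_b[match(cond_a$primer_pair, cond_b$primer_pair), , drop = FALSE]
  ra <- chip_double_ratio(cond_a$k27_flc, cond_a$h3_flc,
                          cond_a$k27_stm, cond_a$h3_stm)
  rb <- chip_double_ratio(cond_b$k27_flc, cond_b$h3_flc,
                          cond_b$k27_stm, cond_b$h3_stm)
  diffs <- ra - rb
  nz <- diffs != 0
  v <- if (any(nz)) sum(rank(abs(diffs[nz]))[diffs[nz] > 0]) else 0
  p <- if (any(nz)) {
    suppressWarnings(stats::wilcox.test(ra, rb, paired = TRUE)$p.value)
  } else {
    1
  }
  structure(list(
    differences = data.frame(primer_pair = cond_a$primer_pair,
                             ratio_a = ra, ratio_b = rb, difference = diffs),
    statistic = v,
    p_value = p,
    direction = c("a_higher", "equal", "b_higher")[
      2 - sign(stats::median(diffs))]
  ), class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> %d primer pairs, V = %g, p = %.3g, %s\n",
              nrow(x$differences), x$statistic, x$p_value, x$direction))
  invisible(x)
}
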