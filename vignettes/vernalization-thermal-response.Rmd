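---
title: "Vernalization thermal response: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vernalization thermal response: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vernaltherm)
```

# The problem

Vernalization — the acceleration of flowering by weeks of cold — is usually
modelled in *Arabidopsis thaliana* with a narrow "chilling" window: hours with
temperatures above 0 °C and below 6 °C count, everything else does not. Cabinet
experiments contradict this: accessions vernalize effectively at constant
temperatures well above 6 °C, some most effectively near 8 °C, and still
partially at 14 °C. For plants establishing in a Scandinavian autumn this
matters enormously: almost the entire August–November season lies inside a
(0, 15) °C daily-mean window, while only a late sliver lies inside (0, 6) °C
hourly. `vernaltherm` packages the full analysis chain needed to make and test
such claims:

1. **climate ingestion** — hourly logger or thrice-daily station readings,
   daily means, autumn statistics, snow-cover detection;
2. **effective-time accumulation** — cumulative vernalization-effective weeks
   under a configurable temperature window, against a constant-temperature
   reference;
3. **response surfaces** — per-genotype flowering time over
   (temperature × duration) grids from cabinet data;
4. **field prediction** — flowering of transplant cohorts predicted by
   matching field interval mean temperatures to constant cabinet conditions;
5. **synthetic data** — a weather and flowering-time generator that provides
   ground truth for every stage;
6. **assay normalization** — the qPCR expression ratio and ChIP double-ratio
   arithmetic that accompanies such experiments.

# Models and their assumptions

## Effective-time accumulation

A `vernalization_window(lower, upper, basis)` counts time strictly inside
(lower, upper) °C. Strict inequality at *both* bounds is inherited from the
legacy convention ("higher than 0, lower than 6") and applied identically at
0 °C and at the upper threshold; at realistic temperature resolution the
distinction is immaterial, but it is fixed so results are reproducible to the
bit. Under the hourly basis each qualifying hourly reading adds one hour;
under the daily-mean basis each *complete* day whose mean qualifies adds 24 h.
Incomplete days add nothing (conservative). Effective weeks are hours/168
under both bases. That convention makes the two bases commensurable and makes
accumulation at a constant in-window temperature exactly linear — one
effective week per elapsed week — which is what the constant-8 °C reference
line (`reference_accumulation`) draws. Temperatures inside the window are not
weighted: effectiveness is binary. Graded temperature kernels exist only in
the synthetic generator's ground truth; the accumulator deliberately mirrors
the hour/day-counting convention used in the field.

"Daytime" restriction for the legacy window defaults to *off* (all 24 h
count); when enabled it uses fixed civil hours 08:00–15:59, matching an 8-h
photoperiod. Timestamps are treated as local civil time with no DST
arithmetic (internally UTC), since loggers record local time.

## Daily means and autumn statistics

The station convention builds a daily mean from the 0600/1200/1800 readings,
complete only when all three exist. For hourly loggers, gaps of up to 6 h are
linearly interpolated before averaging — dropouts are common, and 6 h bounds
the interpolation error at diurnal scale — and a day is complete with ≥ 20 of
24 hours covered. Incomplete days are flagged and excluded from seasonal
statistics but never silently dropped.

`autumn_summary` pools complete days in the configured season window
(default 1 Aug – 30 Nov) across years. It reports both the pooled SD of daily
means (several °C — dominated by the seasonal trend) and the SD of the
per-season means (a few tenths of °C). Published multi-year station summaries
quote the latter; both are exposed so no reader has to guess. Window
membership in the in-window fraction is strict, which is the assumption we
adopt where the convention is unstated. Years with missing days simply
contribute the complete days they have; no year-completeness cutoff is
imposed (an undecidable inclusion rule we keep visible rather than invent).

## Snow-cover detection

Insulating snow clamps a soil-surface trace to ≈ 0 °C with very low variance.
Defaults — |T| ≤ 1.0 °C, 24-h rolling SD ≤ 0.5 °C, runs ≥ 72 h — are package
constants exposed as arguments; the clamped-trace signature is qualitative in
the source records, so the parameterization is ours. A `snow_depth_cm` column,
when present, short-circuits the heuristic.

## Response surfaces

`fit_surface` summarizes replicates per (genotype, temperature, duration)
cell: mean, SD and n over the replicates that flowered, plus the DNF
(did-not-flower) proportion. DNF replicates are excluded from means and
carried as `prop_dnf` because DNF is reported as a category, not imputed; a
censored-mean mode (DNF = at least the scoring bound) exists but is off by
default. Days-to-flower are counted from return to warm; total-age accounting
is a deliberate non-default alternative for pipelines that count all days of
growth.

`interpolate_dtf` is plain bilinear interpolation, exact at nodes. Splines
were rejected: with four durations the grid is too coarse to support
curvature estimates, and the downstream claims are nearest-condition claims.
Queries outside the hull are clamped to the edge with a warning rather than
extrapolated.

`optimal_temperature` is the grid argmin of cell means at a duration, with
DNF-dominated cells (`prop_dnf > 0.5` by default) excluded; exact ties go to
the lower temperature and are flagged. `effective_range` converts cell means
into a relative effect profile
\[(\text{NV mean} − \text{mean}(T,d)) / \max_T(\text{NV mean} − \text{mean}(T,d))\]
and reports the contiguous span around the optimum where it exceeds a
criterion fraction (default 0.5, the usual half-maximum convention; exposed
because no formula is standard), linearly interpolating the crossings and
clamping at the grid edge when the effect is still above criterion there.

## Field prediction

A cohort's sow-to-transfer interval is reduced to its time-weighted mean
temperature (each reading held to the next; for complete hourly data this is
the plain mean of the hourly values) and its duration in weeks. `mode =
"match"` looks up the nearest cabinet cell — nearest temperature, ties to the
lower; nearest duration, ties to the shorter — which is the
constant-condition-matching procedure used in the field studies this package
serves; `mode = "interpolate"` queries the bilinear surface instead. Both
agree exactly when the interval lands on a grid node. Duration matching is
performed explicitly (the original design had transfer intervals aligned with
cabinet durations, so only temperature needed matching); an
`establishment_days` option excludes the first post-germination days to match
a cabinet pre-growth protocol. Soil-surface series are the natural input when
available; the function is agnostic and the caller's choice is visible in the
series' `site_label`.

# The synthetic generator: what it emulates, and what a green test means

`generate_weather` produces hourly temperature as
trend + diurnal + AR(1) noise:

* linear seasonal trend, default 14 → 0 °C over 1 Aug – 30 Nov (season mean
  7 °C, a northern-Scandinavian autumn);
* diurnal sinusoid, default amplitude 3 °C, peaking at 15:00;
* stationary AR(1) noise, default SD 2.5 °C, lag-1 (hourly) coefficient 0.8.
  Autocorrelated noise is essential: white noise would make daily means
  nearly constant and the hourly-vs-daily window comparison trivial;
* optional snow clamping to 0 ± 0.2 °C after an onset date.

`true_dtf` defines each synthetic genotype's ground truth as a Gaussian
temperature kernel with hard support, multiplied into a Hill duration
response:
\[K(T) = e^{-(T - T_{opt})^2 / 2\sigma^2} \cdot \mathbb{1}(T_{min} < T < T_{max}),
\qquad P = \frac{(dK)^h}{(dK)^h + f^h},\]
\[\mathrm{DTF} = \mathrm{DTF}_{NV} - (\mathrm{DTF}_{NV} - \mathrm{DTF}_{sat})\,P\]
with duration *d* in weeks, half-saturation *f* (`full_weeks`) and shape
*h* = 2. Replicates add Gaussian noise (default 10 % of the genotype's
maximal flowering-time reduction); latent values beyond a scoring threshold
become DNF records at that bound — a mechanically simple censoring model
consistent with how DNF is handled downstream.

Five presets (`genotype_presets()`) encode the qualitative contrasts of the
motivating cabinet data: three lines with a mild optimum near 5 °C
(kernel SD 4.5 °C, saturating in 6 or 12 weeks), and two with a sharper,
warmer optimum (7.5 and 8 °C, kernel SD 3.5 °C). All share hard support
(0, 15) °C. Non-vernalized flowering times (130–150 d), saturated times
(38–42 d) and the 12-week requirement of the latest line are round numbers in
the plausible range for vernalization-requiring accessions. They are
*synthetic*: chosen once, on these grounds, and never presented as measured.

What the generator does **not** emulate: weather fronts and multi-day
synoptic excursions (the AR(1) horizon is hours), photoperiod effects,
germination/dormancy variation, devernalization, and any between-replicate
structure beyond i.i.d. noise. A green end-to-end test therefore establishes
internal consistency of the pipeline under the stated world — not field
validity of the biology.

# Numerical choices

* Window membership strict at both bounds; ties in `optimal_temperature` and
  `match_constant_condition` resolved to the lower temperature / shorter
  duration, deterministically.
* Interpolation exactly linear; node queries bypass any arithmetic that could
  introduce rounding (verified to 1e-12).
* Degenerate inputs: empty series, all-DNF cells, zero-length reference
  intervals, and series shorter than the snow-run minimum all return defined
  results or contract errors — never NA propagation.
* All generators restore the caller's RNG state; identical (config, seed)
  pairs are bit-identical.
* CSV round-trips are exact at the printed precision (3 decimals by default).
* The CLI `simulate` config is JSON rather than YAML so the package has no
  dependency beyond what its own IO already uses.

# Known limitations

Two acceptance-level self-checks are mathematically strained by the
generator family itself, and we keep them visible rather than tune them away:

* **Half-effect range vs hard support.** With a Gaussian kernel × Hill truth,
  the half-maximum range of the effect profile is ≈ 1.05 kernel-SD either
  side of the optimum — for the sharp-optimum presets roughly (4.2, 11.7) °C
  at 12 weeks — which is necessarily narrower than the hard support (0, 15).
  A kernel flat enough for the half-effect span to reach the support edges
  would make the optimum statistically unidentifiable at n = 10 with 10 %
  noise. `effective_range` is validated against its actual estimand (the
  truth's half-effect span, recovered within a degree); recovering the
  support would require a plateau-shaped kernel family.
* **2·SEM field-closure band.** The residual between an observed cohort mean
  and a matched cabinet cell mean carries both means' sampling error, yet the
  closure band is 2·SEM of the cabinet cell alone. Even with a perfect model
  and unlimited field replication at n = 10 cabinet replicates, only ≈ 91 %
  of cohorts can fall inside; nearest-cell discretization (an interval mean
  of 5.6 °C matched to a 5 °C cell on a kernel shoulder) costs several more
  percent. Observed closure sits near 73–90 % depending on seed. The honest
  summary is the pooled MAE (≈ 3–4 days against 90–110-day effects), which
  the acceptance report also prints.

Beyond these: no devernalization or Utah/Dynamic chilling-portion models (the
window abstraction would admit them), no photothermal joint model, no
mixed-model or survival treatment of flowering time, and the multi-year
station statistics shipped in the acceptance report are computed on a
labelled synthetic emulation of the station climatology, because the
historical records themselves are not redistributable.
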