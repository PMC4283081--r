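---
title: "Projecting GMS prescribing costs by region, gender and age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting GMS prescribing costs by region, gender and age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmscostsim)
```

## The model

Annual pharmacy cost under Ireland's General Medical Services (GMS) scheme
is driven by four quantities, resolved over 160 strata — the eight former
health board regions x two genders x ten age cohorts (the RGA classes):

* **population** `N_s` — persons in stratum `s`;
* **coverage** `v_s` — the fraction of `N_s` holding a medical card;
* **claims rate** `r_s` — the fraction of card holders who claim at least
  once in the year;
* **average cost per claimant** `c_s` — total claimant pharmacy cost over
  claimants, in euro.

The deterministic cost per population member of stratum `s` is
`k_s = v_s * r_s * c_s`, and the deterministic total scheme cost is
`sum_s N_s * k_s` (`total_cost()`). The Monte Carlo engine propagates
uncertainty around this core: each iteration samples a stratum by its
cumulative empirical probability (inverse CDF over eligible-person shares;
`class_distribution()`, `sample_stratum()`) and draws

```
cost = k_s * (1 + e),   e ~ Normal(0, sd = noise_sd_fraction)
```

so the error ensemble has a standard deviation proportional to cost — 5 %
of cost by default. Noise is multiplicative, not additive: an additive
global SD would let small-cost strata go negative routinely and would weight
uncertainty toward cheap strata. Draws that would still come out
non-positive are redrawn; at 5 % relative noise that is a `> 20 sigma`
event and in practice never fires, so it cannot bias the ensemble. Because
`E[1 + e] = 1`, the ensemble mean is an unbiased estimate of the
expectation `sum_s p_s k_s`, which `simulate_costs()` records alongside the
draws so every run carries its own closed-form check.

Two details of the stratum sampler matter for reproducibility and edge
cases. Intervals are half-open `[lower, upper)`, so `u = 0` selects the
first stratum with positive weight and zero-weight strata (zero-width
intervals) can never be drawn; the final cumulative bound is set to exactly
1 to absorb accumulated floating-point error. Uniform variates (stratum
choice) and normal variates (noise) come from separate child streams of the
run seed, derived by a fixed affine map, so adding draws of one kind never
perturbs the sample path of the other.

## Scenarios

Each input table exists in three variants — minimum, mean, maximum.
For estimated tables the bounds are the 95 % confidence limits
(`ci95_scenarios()`): `mean -/+ 1.96 * SE`, with the binomial standard
error `sqrt(p(1-p)/n)` for claims rates and `sd/sqrt(n)` for average
costs. These are the standard constructions for a proportion and a mean; z
= 1.96 rather than a t quantile because every stratum holds hundreds of
records or more. Bounds are clamped to the table's domain afterwards
([0, 1] for rates, strictly positive for costs) and a message reports any
clamping. For coverage, whose dispersion is observed nationally rather
than per stratum, `historical_scenarios()` offsets the point table by the
gap between the 1996–2011 national series' extremes and its mean, applied
uniformly across strata — the national record does not resolve strata, and
applying its envelope uniformly is the conservative reading.

## Projection rules

* **Claims rate** is held at its 2007 values at every horizon; the national
  rate has been stable (>= 93 %) since the 2010 co-payment was introduced.
* **Average cost** compounds at a historical growth rate:
  `c_s(h) = c_s(2007) * (1 + g)^(h - 2007)` (`extrapolate_avg_cost()`).
  `fit_historical_growth()` estimates `g` as the geometric mean annual
  growth `(last/first)^(1/years) - 1`; on an exactly compounding series
  this coincides with a log-linear regression slope, and it needs no tuning
  parameters.
* **Coverage** anchors the most recent per-stratum eligible counts and
  divides them by each horizon's projected population
  (`project_coverage()`). In the oldest cohorts the raw ratio can exceed
  1.00 (105 projected eligible persons on a projected population of 100
  gives 1.05); any raw rate >= 1.00 is replaced by the adjustment factor
  `lambda` in (0, 0.99], default 0.99 (`adjust_coverage()`), and eligible
  persons are recomputed from the adjusted rate. The hard clamp is the
  simplest rule satisfying the requirement that adjusted rates sit strictly
  below 1.00; `lambda` is an argument so a multiplicative rule can be
  swapped in. One known wrinkle follows from the rule itself: as a
  stratum's population grows, its raw rate can fall from above 1 (capped at
  `lambda`) back into the open window `(lambda, 1)` where it is returned
  unchanged — coverage as a function of population is therefore monotone
  everywhere except across that window.

## The synthetic data generator

No PCRS claims extract or CSO regional projection is distributed, so the
package generates inputs with the statistical structure the analysis
assumes, calibrated to published national aggregates. `synthetic_config()`
holds every knob; all defaults below are fixed study conditions, not free
parameters.

**Claims database** (`generate_claims_db()`): 100 records per stratum per
month over 12 months — 192,000 records, the size and layout of the study's
sample extract. Per-record total cost is lognormal with the stratum mean
from the packaged 2007 average-cost table and a coefficient of variation of
0.30: drug costs are positive and strongly right-skewed (the published
descriptives show maxima far above the third quartile), and a CV of 0.30
gives realistic within-stratum dispersion while keeping 1,200-record
stratum means within ~1 % of their targets. Components split as 80 %
ingredient cost, 15 % dispensing fee, 5 % VAT of the rounded total — the
published decomposition fixes only the 80 % ingredient share; the fee/VAT
split within the remainder is a package choice — with the rounding residual
folded into the ingredient cost so additivity is exact to the cent. Item
counts are `1 + Geometric(mean 2)` with one form per record; these fields
exist so the schema matches the described database, nothing downstream
consumes them.

**Population** (`generate_population()`): a 4.3 million base population for
2007 distributed by configured region, gender and cohort shares, projected
to 2011/2016/2021/2026 on geometric growth paths. Defaults calibrate to the
published aggregates: overall growth 32.6 % by 2026; the 70–74 cohort
+85.4 %; the 75+ cohort from 208,756 to 422,589 persons (the multiplier is
stored as the exact ratio of those printed counts); the Eastern region
share drifting 35.5 % -> 38.2 % and the Southern 14.6 % -> 13.6 %.
Cohorts with explicit multipliers hit their head-count targets exactly and
the rest absorb the residual, so the national total obeys the configured
growth to the person; rounding is hierarchical largest-remainder (cohort
totals first, then cells) to keep those identities exact in integers. Cell
heterogeneity comes from a lognormal perturbation (sd 2 %) of each cell's
growth *increment* — perturbing the increment rather than the level means
an all-ones growth configuration reproduces the base year identically,
which is the natural degenerate case and a useful test fixture.

**Coverage history** (`generate_coverage_history()`): sixteen annual
national rates 1996–2011 whose minimum, mean and maximum equal the
configured triple exactly by construction (an exact-envelope series, not a
free sample): extremes are placed, anchor years forced (30.1 % in 2007,
36.9 % in 2011 by default), and the free years receive a bounded zero-sum
seeded perturbation around the level that delivers the exact mean. The
default envelope (0.28, 0.31, 0.369) spans the coverage contraction of the
mid-2000s and the post-2008 rise to the 2011 anchor.

What the generator does *not* emulate: the real extract's "first 100
observations per cell" selection (a non-random sample of a real database;
cells here are i.i.d. given their stratum), within-person correlation
across months (no person identifier exists in either database), true
regional cohort structure (only national aggregates are calibrated), and
policy-driven coverage shifts. Passing tests therefore demonstrate that the
pipeline's estimators and simulator are correct and internally consistent
under the assumed data-generating process — not that the published euro
projections are reproduced, which would require the undistributed PCRS and
CSO inputs.

## Reporting conventions

`describe_draws()` returns the nine-statistic row used for simulation
summaries (n, mean, SE of mean, SD, min, quartiles, median, max). Quantiles
interpolate order statistics with `stats::quantile(type = 6)` — the Minitab
convention, matching the toolchain the original analysis used — and the
type is an argument because no universal convention exists.
`main_effects()` ranks region, gender and cohort by the range of their
level means; levels with no draws are reported as absent rather than zero,
and when eligible weights are supplied the level means are weighted means
of per-stratum draw means, so any factor's levels recombine exactly to the
grand mean. Currency is euro at two decimals in reports, growth figures at
one decimal; internal computation is never rounded.

## Worked example

```{r pipeline, eval = FALSE}
cfg  <- synthetic_config(seed = 1)
pops <- generate_population(cfg)
db   <- generate_claims_db(cfg)

# scenario tables for average cost; claims rate fixed at 2007
ac_sc  <- ci95_scenarios(estimate_avg_cost(db), avg_cost_se(db))
t1     <- load_rate_table(gms_fixture("claims_rate_2007.csv"), "claims_rate")

# coverage anchored at the 2011 eligible counts, capped below 1
anchor <- round(0.369 * pops[["2011"]]$count)
proj   <- project_coverage(anchor, pops[c("2016", "2021", "2026")])

res <- simulate_costs(
  simulation_spec(horizon = 2016, scenario = 2, seed = 1),
  eligible   = proj[["2016"]]$eligible,
  coverage   = proj[["2016"]]$coverage,
  claims_rate = t1,
  avg_cost   = extrapolate_avg_cost(ac_sc$mean, 0.03, 2016))
describe_draws(res)
main_effects(res)
```

## Numerical choices and limitations

* Stratum sampling weights default to eligible-person shares; population
  shares are a one-argument switch (pass population counts as the weights).
  Eligible share is the default because the simulated quantity is cost per
  person *reachable* by the scheme.
* The 10-cohort scheme of the 2007 tables is canonical; the finer age
  resolution of raw claims files (and a possible 12th cohort above 80) is
  not modelled.
* The packaged tables carry their printed marginal totals as transcribed;
  `validate_consistency()` recomputes weighted marginals and flags
  discrepancies (default tolerance 0.5 % relative) instead of silently
  correcting them. The North-Western female row total is the one printed
  marginal that does not recompute from its cells.
* Eligible persons are rounded half-up to whole persons at reporting time
  only; internal values stay fractional.
* Test and acceptance runs use 20,000–100,000 iterations, 160-stratum
  tables and up to 192,000-record databases; these sizes give Monte Carlo
  standard errors an order of magnitude below every tolerance asserted.
* No variance reduction is applied beyond the RGA stratification itself —
  plain Monte Carlo is the procedure being modelled.
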