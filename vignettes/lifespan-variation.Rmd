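---
title: "Lifespan variation under mortality crises: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifespan variation under mortality crises: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifedisparity)
```

## The problem

Life expectancy at birth, e0, is the mean of the life-table age-at-death
distribution; it says nothing about that distribution's spread. In
populations whose mortality changed smoothly — most Western countries in
the twentieth century — the two moved in lockstep: mortality decline at
young ages both raised e0 and compressed ages at death. Under mortality
*crises*, where death rates at working ages jump and recover within a few
years while old-age mortality barely moves, the mean and the spread can
decouple. This package implements the measurement chain needed to study
that decoupling: life-table construction, dispersion measures, additive
decomposition of their changes by age and cause of death, and trend
segmentation — together with a synthetic data generator that reproduces
the crisis structure so every stage is testable offline.

## Life tables

`lifetable()` converts central death rates m(x) on any strictly
increasing grid into the standard period columns with radix 1, using
q(x) = n·m(x) / (1 + (n − a(x))·m(x)). The mean time lived by decedents
within an interval, a(x), defaults to a Coale–Demeny-style infant rule
a(0) = 0.07 + 1.7·m(0) (capped at 0.5) when the first interval is
[0, 1), and the interval midpoint elsewhere; the difference matters only
in infancy, and `a0_rule = "midpoint"` disables it (the fine-grid
quadrature tests use that mode so the discrete table converges to the
continuous hazard integral). The open interval takes q = 1 and
e(ω) = 1/m(ω), i.e. an exponential tail at the observed open-age rate;
the same tail closes the entropy and Gini integrals. If the q(x) formula
exceeds 1 (catastrophic rates), the interval absorbs all remaining
deaths, which keeps Σd(x) = radix exact. Two robustness variants mirror
common data-quality checks for the region: `inflate_infant_rates()`
(doubled age-0 rates before 1990, tapering linearly to +10 % at 2000 and
constant after) and `lifetable_conditional()` (radix reset at a chosen
age, removing early-life mortality from the dispersion measures).

## Dispersion measures

Life disparity e† = ∫ d(a) e(a) da is the average remaining life
expectancy at the ages people die. The discrete evaluator weights each
closed interval's remaining expectancy at the mean age at death:
d(x)·[(1 − a(x)/n)·e(x) + (a(x)/n)·e(x+n)], plus d(ω)·e(ω). The
linear interpolation is what makes the discrete sum converge to the
integral — tested against a 0.01-year quadrature oracle on Gompertz
hazards.

The *threshold age* a† is where a marginal mortality improvement has
zero effect on e†. There is no closed form on an arbitrary discrete
schedule, so `threshold_age()` locates it operationally: rates in a
1-year band centred at a trial age are cut by 1 % (pro rata to the
band's overlap with each interval), the table is rebuilt, and the sign
change of the resulting Δe† is refined by root finding. The continuity
of the band perturbation is what lets the crossing be bracketed and
polished to |Δe†| < 1e−6 years. When several crossings exist the oldest
below the open interval is returned (the demographically meaningful one
for adult schedules) and all are reported.

Keyfitz entropy is computed *independently* of e† as
H = −∫ l ln l dx / e0 by trapezoid (the two are equal in the continuum,
since −∫ l ln l = ∫ l μ e by Fubini), and the identity H·e0 ≈ e† is a
cross-check between two independently coded paths, not a definition.
The life-table Gini uses G = 1 − (1/e0)∫ l² dx and is checked against a
brute-force mean-absolute-pairwise-difference oracle on the d(x) atoms.

Cross-population spread uses the population (n-denominator) standard
deviation over the mean: the study countries are a complete set, not a
sample. The quadrant analysis classifies yearly (Δe0, Δe†) pairs by
sign, pooled across populations within periods, with normal-approximation
binomial 95 % intervals p ± 1.96·√(p(1−p)/n). Exact-zero differences
are counted separately and excluded from denominators by default
(`drop_zero = FALSE` keeps them); both choices are reported so
sensitivity is one flag away.

## Decomposition

`horiuchi_decompose()` implements the line-integral decomposition: the
covariate vector moves along the straight line between the two
observation points in n equal segments, and at each segment midpoint
covariate i is advanced/retarded by half a step, the functional
difference accruing to cᵢ. The straight-line path is the natural choice
absent any information about the intermediate trajectory; symmetry
(end→start negates every cᵢ) and additivity (Σcᵢ = Δf up to a residual
shrinking quadratically in the step count) are tested rather than
assumed. The default of 20 steps keeps the residual below
1e−6·max(1, |Δf|) for year-over-year-sized changes; the pipeline, which
decomposes across 6–20-year periods with much larger rate swings, uses
80 steps to hold the same tolerance and aborts if any residual exceeds
it.

Cause-of-death work uses seven broad groups. The ICD-10 ranges for the
alcohol-attributable, circulatory, transport and other-external groups
follow the published grouping for alcohol-amenable mortality;
infectious & respiratory (A00–B99, J00–J99) and cancers (C00–C97) are
package conventions, stated as such in the docs. Overlaps resolve by
first match in priority order (alcohol first). Cause-specific rates are
m(x)·p(x,c), so summing causes reproduces the all-cause schedule to
machine precision, and everything at or above the truncation age
(default 85, where cause certification quality degrades) sits in "rest".
Cause decompositions are evaluated entirely on the abridged 5-year grid
so covariates and functional share one grid; the abridged totals differ
from single-age totals by a small discretization amount, which the tests
bound.

## Trends

Smoothing is Whittaker-style penalized least squares on log rates with
second-order difference penalties along age and year, solved exactly by
eigendecomposition of the two penalty matrices and tuned by GCV on a
log-spaced grid. This is deliberately simpler than Poisson P-spline
machinery: the downstream contract is only the ±0.5 %/year
classification of ρ(x,t) = −100·Δₜ ln m(x,t), and the penalty null
space (bilinear log surfaces pass untouched) plus a seeded denoising
test pin the behaviour that matters. Zeros are floored at 1e−6 before
logging.

Period segmentation uses divisive hierarchical change-point detection
with the two-sample energy statistic (exponent 1) on the standardized
series: at each stage the best split over all current segments is tested
against a within-segment permutation null (199 permutations,
α = 0.05, minimum segment 5 years — the algorithm family fixes none of
these, so they are package defaults flagged for sensitivity analysis)
and accepted splits recurse. Standardization makes the procedure
affine-invariant; the seed makes it reproducible. Operating
characteristics are tested directly: ≥95 % recovery of 5σ level shifts
within ±1 year, and false-positive rate within Monte-Carlo error of α
on pure noise.

`assign_periods()` maps statistical breaks to canonical analysis
boundaries {1980, 1988, 1994, 2000}. A break b snaps to boundary c when
|b − (c − 1)| ≤ 3: boundaries are read as "period runs through c − 1",
so the comparison is against the last complete year before the boundary
(this is what makes a statistical break at 1976 belong to a period
ending 1979). More distant breaks are kept verbatim and labelled
non-canonical.

## The synthetic generator

`make_surface()` builds m(x,t) = μ(x)·factor(x,t) from a Siler hazard
with a Gaussian young-adult hump and a schedule of age-band multipliers.
The pinned `cee_male_params()` calibration gives e0 ≈ 65.1 and
e† ≈ 16.1 years — the stagnation-era levels of the region's male
populations (e0 roughly 63–70, e† 13–19). The two-country fixture pairs
a steadily improving country (0.7 %/year decline at all ages) with a
crisis country whose working ages (20–60) drift ~12 % worse over
1960–1979, improve through the 1980s, jump sharply in 1988 to a peak
factor of 1.5 and stay high through 1999, then step down and decay from
2000 — the stagnation / improvements / deterioration / divergence /
convergence sequence. The 1988 and 2000 transitions are deliberately
abrupt so change-point recovery has a sharp target. Cause-proportion
tables come from parametric age profiles (logistic rises for circulatory
and cancers, working-age Gaussians for alcohol/transport/other-external,
a declining infectious profile, flat residual), with crisis-year weights
tied to the schedule's working-age factor so that cause change
concentrates where rate change happens.

What the generator does *not* emulate: stochastic rate noise is optional
(`sample_death_counts()`) and off by default, so acceptance-style checks
are exact; there are no cohort effects, no migration, no age heaping or
other data-quality artefacts, and the cause profiles are far smoother
than real certification data. Passing tests therefore demonstrate that
the *methods* behave as specified on data with the assumed structure —
not that any substantive conclusion about a real population follows.

## Numerical choices and problem sizes

Decomposition residual tolerance is 1e−6·max(1, |Δf|) (pipeline aborts
above it); threshold-age root refinement to ~1e−8 years in age;
quadrature oracles in the tests use 0.01-year grids; constant-hazard
closed-form checks use a 0.1-year grid to age 400 so the open interval
is negligible. The test suite's change-point operating characteristics
use 200 replicates of 30-year series; the pipeline fixtures span
1960–2014 (55 years × 111 ages × 2 countries), sizes chosen to exercise
every stage at full fidelity while keeping the whole suite and the
acceptance script in the minutes range on one core.

One structural choice deserves a note: the package is an analysis
pipeline rather than a single estimator, so instead of one `fit()`
function it exposes one classed S3 result per analysis object —
`lifetable` (print/summary/plot), `decomp_result`, `improvement_surface`,
`period_segmentation`, `quadrant_summary` — all with base-R internals.
`run_pipeline()` strings the stages together, writes one delimited file
per stage with a units header, and a manifest sufficient to re-run the
bundle byte-for-byte.

## Known limitations

* The life-table closure is the standard rate-to-probability conversion;
  populations with strong within-interval rate gradients (very wide
  abridged intervals) inherit its bias.
* The threshold age is defined through a finite 1 % perturbation; for
  schedules where e†'s sensitivity is extremely flat near the crossing,
  the reported age is a root of that finite-difference function, not of
  the analytic derivative.
* The HMD/HCDB readers target one documented dialect each (plus the
  package's own fixtures); other layouts need adapters.
* The change-point permutation test treats years as exchangeable within
  segments; strongly autocorrelated series will over-segment, which is
  visible in the deterministic fixture where smooth trends yield
  additional significant breaks beyond the regime jumps.
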