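# lifedisparity

Tools for analysing **lifespan variation under mortality crises**: when a
population's death rates swing abruptly — as they did for working-age men
in Central and Eastern Europe between the 1960s and the 2010s — life
expectancy at birth (e0) and the *dispersion* of ages at death can move
independently, and looking at e0 alone hides a whole dimension of
population health. This package builds the full analysis chain for that
question from age-specific death rates:

* **Period life tables** from single-year or abridged m(x) schedules,
  with the standard q(x) = n·m(x) / (1 + (n − a(x))·m(x)) closure, an
  open interval closed by e(ω) = 1/m(ω), and robustness variants
  (infant-rate inflation, conditioning on survival to a given age).
* **Dispersion measures**: life disparity
  e† = ∫ d(a) e(a) da — the average remaining life expectancy at the ages
  people die, i.e. life-years lost per death — plus the threshold age a†
  (below which saving lives compresses the age-at-death distribution and
  above which it expands it), Keyfitz entropy H = e†/e0, and the
  life-table Gini coefficient G = 1 − (1/e0)∫ l(x)² dx.
* **Decomposition**: the Horiuchi line-integral method
  f₂ − f₁ = Σᵢ ∫ (∂f/∂xᵢ) dxᵢ = Σᵢ cᵢ, attributing a change in e0 or e†
  additively to every single-age rate, or to every 5-year-age-group ×
  cause-of-death rate using a seven-category ICD-10 grouping
  (alcohol-attributable, circulatory, transport accidents, other external,
  infectious & respiratory, cancers, rest; causes truncated at age 85).
* **Trend tooling**: penalized 2-D smoothing of log-rate surfaces, annual
  rates of mortality improvement ρ(x,t) with a ±0.5 % "little change"
  band, divisive energy-statistic change-point detection with a
  permutation test for segmenting series into analysis periods, and a
  quadrant analysis of paired yearly changes (Δe0, Δe†).
* **Synthetic data**: a deterministic generator (Siler hazard + Gaussian
  young-adult hump + regime-driven crisis multipliers) and HMD-style
  Mx 1x1 / cause-table readers and writers, so the entire pipeline runs
  and is tested without any external downloads.

## Worked example

```r
library(lifedisparity)

# a CEE-male-style schedule and its dispersion summary
lt <- lifetable(siler_hazard(0:110, cee_male_params()), 0:110)
summary(lt)
#> e(0)            65.144 years
#> e-dagger        16.057 years
#> entropy H       0.2468
#> Gini            0.1859
#> threshold age    67.15 years

# a working-age mortality crisis: +50 % on ages 20-60
mx <- siler_hazard(0:110, cee_male_params())
crisis <- mx * ifelse(0:110 >= 20 & 0:110 <= 60, 1.5, 1)
surf <- mortality_surface(cbind(mx, crisis), 0:110, c(1990, 1994))
d <- decompose_by_age(surf, 1990, 1994, functional = "edagger")
round(d$total, 3)
#> [1] 1.276
```

The decomposition says the crisis adds about 1.28 years of life
disparity, and `d$contributions` shows the gain concentrated at the
perturbed working ages — deaths there land well below the threshold age,
so they widen the age-at-death distribution.

The full pipeline (life tables → dispersion series → change-point
segmentation → improvement surfaces → quadrant analysis → age and
age×cause decompositions, each stage written as a TSV with a JSON
manifest) runs off one config object:

```r
res <- run_pipeline(run_config(output_dir = "run1"))
res$manifest$period_labels
#> [1] "stagnation" "improvements" "deterioration" "divergence" "convergence"
```

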