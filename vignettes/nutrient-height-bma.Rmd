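---
title: "Dietary N and P intake and adult height: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary N and P intake and adult height: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Mean adult male height varies by roughly 23 cm across countries, and the
gap between rich and poor countries has widened across the 1960s, 1970s
and 1980s birth cohorts. A nutritional reading of this pattern treats
dietary nitrogen (N, mostly protein) and phosphorus (P) as the building
blocks of growth: countries whose diets carry more N and P per person --
typically diets richer in animal-source foods -- should show taller
cohorts and faster height gains. This package implements the full
analysis chain for that question on country-by-cohort panels: intake
construction from food-balance and food-composition tables, diet-group
classification, symmetric (reduced major axis) regression, all-pairwise
country-difference models, and Bayesian model averaging (BMA) over two
panel regressions, exercised end to end on synthetic data with known
ground truth.

## Intake construction

Per-capita annual intake of N (and P) for country $i$ and cohort $t$ is

$$\mathrm{N}_{it} = \frac{\sum_{\text{years } y} \sum_{\text{groups } f}
  q_{ify} \, c^{N}_{f}}{\#\text{years}},$$

where $q_{ify}$ is the food-balance quantity (kg person$^{-1}$ y$^{-1}$)
of food group $f$ in year $y$ and $c^{N}_f$ is the group's mean N
concentration (kg N per kg food). Concentrations come from item-level
composition databases by a two-stage mean: an item reported by several
databases first gets the cross-database mean, and the group value is the
mean over its items (`average_food_group_concentration()`).

Each cohort's years are its growth window: 1961--1989 for men born in
the 1960s, 1971--1999 for the 1970s, 1981--2009 for the 1980s
(`growth_window()`). Years with no records inside a window are dropped
from the denominator with a warning (the formula divides by the number
of years actually averaged); food groups missing within an otherwise
recorded year contribute zero, i.e. absent rows are treated as missing
at the year level and explicit zeros as true zeros. The N:P ratio is a
mass ratio; no calorie weighting and no bioavailability adjustment
(phytate-bound plant P) is applied -- the quantity is intake, not
absorption.

A country is **animal-dominated** when
$(\mathrm{N_{animal}/N_{plant}}) + (\mathrm{P_{animal}/P_{plant}}) > 2$,
else **plant-dominated**. The threshold is strict: the measure-zero
boundary (sum exactly 2) is folded into the plant-dominated side so the
rule is exhaustive. Classification is computed per cohort; when a single
per-country label is needed the 1980s-cohort window is used.

## Association analyses

`rma_fit()` performs reduced major axis regression, appropriate because
both height and estimated intake carry error: the slope is
$\mathrm{sign}(r)\,s_y/s_x$, and the reported $r^2$ is the squared
Pearson correlation (identical for RMA and ordinary least squares, so no
choice needs to be made for reporting).

`pairwise_differences()` builds signed differences for all $n(n-1)/2$
unordered country pairs within a cohort, oriented lexicographically.
`glm_pairwise_fit()` then fits least squares *without an intercept*:
signed differences are antisymmetric under orientation reversal, so an
intercept is not identifiable under any orientation convention and
omitting it makes inference orientation-invariant. An `absolute = TRUE`
switch instead takes absolute values of the response and predictors,
since published descriptions of this design are ambiguous between the
two readings; neither is asserted as canonical. Per-predictor partial F
statistics are drop-one (Type-III-style) nested comparisons via
`stats::drop1()`, matching the convention of one F per predictor in a
joint model. Pairs sharing a country are not independent; no correction
is applied, which mirrors the design this reproduces and is a known
caveat for the p-values (the F statistics are used descriptively, as
relative variable weights).

## The two BMA regressions

**Levels model.** Height levels are modelled jointly for the two diet
groups with one error variance:

$$height_{it} = \sum_{k=1}^{2} \big[\beta_{1k} + \alpha_{tk} +
  \textstyle\sum_j \beta_{jk} x_{jit}\big]\, I(\omega_{itk} = 1) +
  \varepsilon_{it}, \qquad \varepsilon_{it} \sim N(0, \sigma^2),$$

with covariates $x_j$: N, P, N:P, GDP, GDP growth, calories, urban
share, and the two animal/plant partition ratios (optionally HDI and %
low-birth-weight infants). In the design matrix each covariate owns two
group-specific columns ($x \cdot I(\text{group})$). One inclusion
indicator per covariate switches *both* group columns together: the
groups share the model structure (and $\sigma^2$) but not the
coefficient values. This reconciles a single written coefficient set
with group-specific posterior densities and is flagged as an
interpretation. Per-group intercepts and per-group cohort dummies are
always included, never selected over.

**Differences model.** For countries with complete consecutive-cohort
pairs, the response is the height change between cohorts $t$ and $t+1$
and the covariates are the N and P intake *levels* plus differences of
the remaining terms; with complete data for three cohorts in $m$
countries this gives $2m$ rows (108 rows at $m = 54$). The model is
ungrouped (intercept plus cohort-pair dummy always included). Which
cohort supplies the level terms is not pinned down by the written model;
the package defaults to the earlier cohort of each pair and exposes
`level_cohort = "later"` as a switch. GDP growth is likewise
under-specified; the generator treats it as mean annual growth (% per
year) over the cohort window.

## Prior and posterior computation

Selectable coefficients carry a Zellner g-prior after projecting out the
always-included block $W$: with $\tilde Z = (I - P_W) Z_M$,

$$\gamma_M \mid \sigma^2 \sim N\!\big(0,\; g\,\sigma^2 (\tilde Z'\tilde
Z)^{-1}\big), \qquad p(\alpha) \propto 1, \qquad p(\sigma^2) \propto
1/\sigma^2,$$

giving the closed-form log evidence
$-\tfrac{\nu}{2}\log 2\pi - \tfrac12 \log|W'W| + \log\Gamma(\tfrac\nu2)
 - \tfrac{k_M}{2}\log(1+g) - \tfrac{\nu}{2}\log(S_M/2)$
with $\nu = n - p_W$ and
$S_M = RSS_W - \tfrac{g}{1+g}(RSS_W - RSS_{W+Z_M})$. The scale defaults
to the benchmark ("BRIC") rule $g = \max(n, K^2)$ with $K$ the number of
selectable columns, a standard default in the model-averaging
literature; no prior was asserted by the original analysis. The model
space prior is uniform over the $2^k$ subsets, with a binomial
alternative exposed because nothing in the problem fixes this choice.

`bma_fit()` enumerates all subsets exactly up to a cap (default
$k \le 20$; all designs in this package have $k \le 11$, i.e. at most
2048 models). Above the cap, an MC3 sampler walks model space with
single-covariate add/drop Metropolis proposals. MC3 PIPs and moments are
computed from posterior weights renormalised over the set of *visited*
models -- each visited model's evidence is exact, so this estimator
converges as soon as all non-negligible models have been visited, much
faster than raw visit frequencies (which are kept in the diagnostics for
comparison).

Posterior summaries follow the mixture logic: a covariate's PIP is the
summed probability of models containing it; conditional moments are
model-probability-weighted mixtures with the conditional variance from
the law of total variance across models; the full coefficient posterior
is a point mass $1 - \mathrm{PIP}$ at zero plus the continuous
conditional component. `coefficient_density()` exports that two-part
density; the continuous part is drawn as a moment-matched scaled-t with
$\nu$ degrees of freedom, an approximation to the exact model mixture
that is accurate whenever one or a few similar models dominate.

### Numerical choices

* Evidence uses QR residualisation and Cholesky solves of the projected
  cross-product; a model whose columns are collinear given $W$ raises a
  collinearity error naming the columns (tolerance
  $\sqrt{\epsilon}\,\max_j \sqrt{C_{jj}}$ on the Cholesky diagonal).
* The g-prior shrinks conditional means by $g/(1+g)$; with the BRIC
  default and $n = 240$ this is a 0.2% attenuation, visible only in
  noiseless checks.
* MC3 proposals that hit a collinear model are rejected outright; the
  chain is deterministic given its seed.
* All randomness in the package flows from one master seed through
  `split_seeds()` (one stream per generated table), so adding an output
  table never perturbs the others.

## The synthetic-data generator

`simulate_panel()` emulates the joint structure of the real data
sources without reproducing any of them: 80 countries (configurable) by
three cohorts, two diet groups, and the printed variable ranges -- N
intake 3.3--23.7 kg y$^{-1}$, P intake 0.41--2.76 kg y$^{-1}$, calories
1879--3721 kcal d$^{-1}$, heights around 160--183 cm. Specifically:

* Intakes are uniform within group-specific sub-ranges, the
  animal-dominated group occupying the upper half of the N range;
  out-of-range draws are resampled, never clipped, to avoid boundary
  atoms. The N:P ratio is drawn U[6.5, 10.5], a dispersion choice
  consistent with group mean ratios near 9.0 (rich) and 7.2 (poor);
  within-group dispersion is a generator choice, as only group means and
  ranges are documented for the real data.
* Cohort trends default to the documented rich/poor asymmetry: N +12.1%
  (animal group) vs +7.0% (plant group) and P +7.6% vs +6.01% from the
  first to the last cohort, implemented as food-group quantities linear
  in calendar year. Because the growth windows are symmetric 29-year
  spans, a linear series makes each window mean equal the value at the
  window's central year, so `build_intake_panel()` recovers the
  generator's per-cohort targets *exactly* (to machine precision) -- the
  round trip is an identity, not an approximation.
* Food-group quantities are obtained by inverting the 2x2 linear system
  (two groups per origin, N and P constraints); the fixed taxonomy's
  concentration ratios bracket the realised per-origin N:P range so the
  solution is positive.
* The animal/plant partition ratios drift mildly across cohorts (upward
  in the animal group), keeping the classification on the correct side
  at every cohort while making cohort differences of the ratios
  informative.
* Heights are the levels-model linear predictor (per-group intercepts
  164/158 cm, per-group cohort effects defaulting to +1.5 cm total for
  the animal group and 0 for the plant group, true covariate
  coefficients from the config) plus Gaussian noise with `noise_sd = 2`
  cm. The observed rich-minus-poor change in generated panels exceeds
  the configured 1.5 cm cohort effect, because the group-asymmetric
  intake trends also feed height through the true coefficients -- both
  channels are part of the emulated condition.
* Composition source tables scatter item values around the true group
  concentrations with recentred deviations, so the two-stage averaging
  recovers the truth exactly and the cross-database averaging path is
  exercised.

What the generator does **not** emulate: real food-group taxonomies
(four stylised groups stand in for the full list), geographic or
temporal autocorrelation, measurement error in heights beyond i.i.d.
noise, missing-data patterns of real compilations, and the nonlinear
GDP/HDI saturation visible in real data. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under
the stated model, not robustness to the full messiness of the real
sources.

## Problem sizes used in the checks

The validation suite runs at sizes chosen to make every check sharp yet
quick: evidence quadrature on $n \le 15$, $k \le 2$ instances (where
dense grids are exact to well below the $10^{-4}$ comparison
tolerance); sampler-vs-enumeration agreement on $k \le 10$ instances at
50 000 draws; and parameter recovery over 100 generated panels at the
study scale of 80 countries by 3 cohorts with one true covariate
(standardized effect 0.8 on the N:P ratio) among 8 nulls. Under the
uniform model prior the prior inclusion probability is 0.5, so null
covariates are required to stay below 0.65 mean PIP; in practice they
sit near 0.02 and the true covariate above 0.99.

## Known limitations

* Ecological inference: all associations are across countries, not
  individuals; nothing here supports individual-level conclusions.
* The pairwise-difference model ignores the dependence between pairs
  sharing a country.
* The structural-equation analysis sometimes paired with this design is
  out of scope, as are nonlinear saturating fits for GDP/HDI.
* The t-density export in `coefficient_density()` is moment-matched
  across models rather than the exact mixture; PIPs and moments are
  exact (under enumeration) regardless.

## A worked example

```{r}
library(npheight)

cfg <- run_config(generator = panel_config(n_countries = 80), seed = 1)
bundle <- run_pipeline(cfg)
print(bundle)
summary(bundle$bma_levels)
plot(bundle$bma_levels, covariates = c("NP", "N"))
```
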