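# npheight

Tools for studying how per-capita dietary nitrogen (N) and phosphorus
(P) intake relate to mean adult male height across countries and birth
cohorts (1960s, 1970s, 1980s).

Height is a nutrition-sensitive trait: N (mostly protein) and P are the
elemental building blocks of growth, and diets rich in animal-source
foods carry more of both. The package implements the full analysis chain
for country-by-cohort panels, for epidemiologists and biogeochemists
working on diet quality:

* **Intake construction** — per-capita annual N and P intake per country
  and cohort from a long food-balance table and food-composition
  databases, `N_it = (Σ_years Σ_groups quantity × concentration) /
  #years`, averaged over each cohort's growth window (1961–1989,
  1971–1999, 1981–2009); the N:P mass ratio; and the diet-group
  indicator: a country is *animal-dominated* when
  `(animal N / plant N) + (animal P / plant P) > 2`, else
  *plant-dominated*.
* **Association analyses** — reduced major axis regression of height on
  intake (slope `sign(r)·sd(y)/sd(x)`); all-pairwise country-difference
  linear models without intercept, with drop-one partial F statistics;
  cohort-change tables.
* **Bayesian model averaging** — a joint two-group levels model

  `height_it = Σ_k [β_1k + α_tk + Σ_j β_jk x_jit] · I(ω_itk = 1) + ε_it`

  and an ungrouped cohort-differences model, averaged over all covariate
  subsets under a Zellner g-prior (`g = max(n, K²)`) with exact
  enumeration or an MC3 add/drop sampler; posterior inclusion
  probabilities (PIPs) and spike-plus-conditional coefficient densities.
* **Synthetic data** — a generator reproducing the study's structure
  (~80 countries × 3 cohorts, two diet groups, N intake 3.3–23.7 kg/y,
  P 0.41–2.76 kg/y, calories 1879–3721 kcal/d, heights ≈160–183 cm,
  group-asymmetric intake trends) with a full ground-truth record for
  recovery testing.

See `vignettes/nutrient-height-bma.Rmd` for the models, priors and
design choices in detail.

## Worked example

```r
library(npheight)

cfg <- run_config(generator = panel_config(n_countries = 80), seed = 1)
bundle <- run_pipeline(cfg)
print(bundle)
```

```
npheight report bundle (seed 1 )

Stage row accounting:
       stage rows_in rows_used rows_dropped seconds
        data   15680     15680            0   0.152
      intake     240       240            0   0.249
 association     240       240            0   0.020
         bma     240       240            0   0.388

RMA of height on intake:
 predictor  slope intercept r_squared   n
         N  1.207     155.3     0.700 240
         P 10.744     154.6     0.485 240
        NP  5.515     124.5     0.210 240
       Cal  0.011     139.8     0.692 240

Top levels-model PIPs:
   NP   Cal aN_pN     P aP_pP
1.000 0.160 0.029 0.026 0.016
```

Reading this: the pipeline generated a synthetic 80-country × 3-cohort
panel (15 680 intake rows), built the intake panel, and fitted the
association and BMA stages. Height rises with N intake (RMA slope
1.21 cm per kg N y⁻¹, r² = 0.70 on this draw). The default generator
truth puts a nonzero effect on the N:P ratio and N intake; the levels
BMA correctly assigns the N:P ratio a posterior inclusion probability of
1.00 while pure-null covariates stay near the bottom. Individual fits
are available directly:

```r
f <- rma_fit(bundle$analysis_panel$NP, bundle$analysis_panel$height)
print(f)
#> Reduced major axis fit (n = 240 )
#>   slope: 5.51525   intercept: 124.475   r^2: 0.2096
```

A thin command-line wrapper exposes the same stages
(`simulate`, `intake`, `associate`, `bma`, `run`):

```sh
Rscript scripts/npheight.R run --seed 1 --countries 80 --outdir out/
```

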