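# borealrings

Tree-ring chronology construction and climate–growth analysis for boreal
conifers, built around the workflow used for black spruce (*Picea
mariana*) and white spruce (*Picea glauca*) in interior Alaska: signal-free
multi-curve regional curve standardization (RCS), static and moving-window
climate correlations with bootstrap significance, boosted-regression-tree
(BRT) analysis of nonlinear climate and habitat effects, and tree-ring
carbon-isotope gas-exchange physiology (Δ¹³C, Ci/Ca, Ci, iWUE).

## Who this is for

Dendroecologists and plant ecophysiologists who need a tested, scriptable
version of this analysis chain — from raw Tucson/RWL ring-width files and
per-tree metadata through pith correction, detrending, chronology
statistics, climate response, habitat stratification and isotope-derived
water-use efficiency — plus a seeded synthetic-data generator with known
ground truth so every estimator can be validated by parameter recovery.

## The core methods

* **Multi-curve RCS.** Ring width is modelled as
  `w = f_g(age) · C(year) · m_tree · ε`; the regional curve `f_g` (per
  growth-rate class, >40 series per class) is the biweight mean width by
  cambial age smoothed by a penalized cubic spline with a 50%
  frequency cutoff at 10% of the maximum age. Indices are ratios of
  observed to expected width; the chronology is the per-year Tukey
  biweight robust mean (c = 9), truncated below 50 trees and rescaled to
  mean 1.0 over its retained span.
* **Signal-free iteration.** Raw widths are repeatedly divided by the
  current chronology and the curves refit from the signal-free
  measurements (tolerance 0.002, fewer than ten iterations), undoing the
  absorption of common signal into the age curve that biases single-pass
  RCS when tree age and calendar year are confounded.
* **Climate–growth correlation.** Monthly May–August temperature and
  precipitation for the growth and previous year (precipitation
  log-transformed), Pearson correlations over the record and in 25-year
  moving windows, significance from a stationary bootstrap of years on the
  Fisher-z scale, and a block-bootstrap variance test for low-frequency
  change in the moving correlations.
* **BRT models.** Gradient boosting (tree complexity 2, learning rate
  0.001, bag fraction 0.5, ≤30000 trees by 10-fold CV) for nonlinear
  climate–growth form, habitat controls on recent growth, relative
  influence, partial dependence and interaction screening.
* **Isotope physiology.** Δ¹³C = (δₐ − δ_tree)/(1 + δ_tree/1000);
  Ci/Ca = (Δ − 4.4)/(27 − 4.4); iWUE = (Ca − Ci)/1.6, with a −1.33‰
  cellulose offset for the gas-exchange chain and a random-forest
  ring-age adjustment (period effects at constant ring age).

See `vignettes/boreal-spruce-growth.Rmd` for assumptions, parameter
defaults and numerical details.

## Worked example

```r
library(borealrings)

cfg    <- synth_config(seed = 1)          # 150 trees, 150 years, known truth
cohort <- generate_cohort(cfg)
fit    <- signal_free_rcs(cohort$series, n_boot = 200, seed = 1)
fit
#> <signal_free_rcs> 150 trees, 3 curve(s), 9 iteration(s) (not converged)
#> <chronology> 1875-2013 (139 yr), depth 52-150, mean 1.000000

cv   <- climate_variables(cohort$climate)
cors <- static_correlations(fit$chronology, cv, n_boot = 1000, seed = 1)
head(cors[order(-abs(cors$r)), ], 6)
#>    variable     r ci_low ci_high significant   n
#>       p_aug  0.53   0.37    0.66        TRUE 139
#>  t_aug_prev -0.50  -0.63   -0.35        TRUE 139
#>       t_aug -0.46  -0.58   -0.31        TRUE 139
#>       t_may -0.44  -0.60   -0.24        TRUE 139
#>  t_may_prev -0.42  -0.58   -0.23        TRUE 139
#>       t_jun -0.36  -0.54   -0.13        TRUE 139
```

The chronology is truncated where fewer than 50 trees contribute, has mean
exactly 1.0 over its retained span, and correlates at r = 0.962 with the
generator's true common signal (`cohort$truth$signal`). The correlation
table recovers the structure the generator encodes: growth rises with
August precipitation and falls with warm growing seasons, in both the
current and the previous year.

The isotope chain converts per-tree cellulose δ¹³C into period-level
physiology (here on synthetic records; note the rising Ci and iWUE under
near-constant Ci/Ca as atmospheric CO₂ rises):

```r
ph <- physio_series(generate_isotopes(cfg, cohort)$records,
                    generate_reference(cfg), seed = 1)
ph[ph$species == "white_spruce",
   c("period", "n_trees", "delta_adjusted", "ci_over_ca", "ci", "iwue")]
#>     period n_trees delta_adjusted ci_over_ca  ci iwue
#>  1895-1904      70           19.8      0.683 200 58.3
#>  1930-1949      75           19.6      0.671 210 64.5
#>  1950-1959      75           19.4      0.665 215 67.7
#>  1993-2002      75           19.6      0.672 243 74.1
#>  2003-2012      75           19.7      0.677 251 75.0
```

A one-command pipeline (`run_pipeline()`, or
`inst/scripts/run_pipeline.R` from a shell) runs synthetic-data
generation, loading, detrending, correlation, isotope and habitat stages
from a single YAML config and writes CSV outputs plus a reproducibility
manifest; identical config and seed give byte-identical outputs.

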