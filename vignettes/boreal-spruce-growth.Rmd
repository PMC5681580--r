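---
title: "Methods: signal-free RCS chronologies, climate-growth analysis and isotope physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal-free RCS chronologies, climate-growth analysis and isotope physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealrings)
options(borealrings.verbose = FALSE)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical choices behind them, and what the
synthetic-data generator does and does not emulate. The worked numbers in
the README are produced by the code; this document states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The detrending model

A measured ring width is modelled multiplicatively,

$$w_{t}(y) \;=\; f_g\!\big(a_t(y)\big)\; C(y)\; m_t\; \varepsilon_{t,y},$$

where $f_g$ is the expected width at cambial age $a$ for growth-rate class
$g$ (the *regional curve*), $C(y)$ is the common year signal shared by all
trees (the chronology, mean 1), $m_t$ is a tree-level growth multiplier and
$\varepsilon$ is multiplicative noise. Regional curve standardization (RCS)
estimates $f_g$ by aligning rings on cambial age, so each ring-width index
$w/f_g(a)$ is an estimate of $C(y) m_t \varepsilon$. Cambial ages include
the estimated number of rings missing between the innermost measured ring
and the pith; the missing radial distance is recovered from the innermost
complete arc by the geometric method, $r = c^2/(8h) + h/2$ for chord $c$
and arc height $h$, and converted to a ring count by dividing by the mean
width of the first ten measured rings (rounded half to even; field
protocols state no rounding rule, and unbiased rounding is the neutral
choice). Series with neither pith nor a usable arc are
excluded at load time. On plots with a known fire history all rings from
the fire year onward are removed; whether the fire year itself is removed
is configurable, and the conservative reading (remove it) is the default.

### Multi-curve grouping

Four-curve RCS splits the cohort into four growth-rate classes and fits a
separate curve to each, which protects the chronology from changes over
time in the growth-rate mix of the sample. Classes must each hold more
than 40 series; the requested number of curves is reduced automatically
until that holds (150 trees therefore yield three curves, 100 trees two).

The ranking metric deserves a note, because the obvious choice is subtly
wrong. Ranking trees by their whole-life mean ring width conflates growth
rate with age structure: an old tree carries many narrow old-age rings, so
at a given intrinsic growth rate older trees rank lower. Within a class
the oldest ages are then populated only by that class's intrinsically
fastest growers, which biases the upper tail of the regional curve upward;
the signal-free iteration (below) feeds that tilt back into the chronology
and amplifies it. The package therefore ranks trees by their mean ring
width over a common juvenile cambial-age band (ages 1-40 by default,
`rank_age_band`), which compares like with like and removes the
within-class correlation between growth rate and germination date. This is
the package's own design choice; with it, the signal-free estimator beats
single-pass RCS on every seeded replicate of the standard synthetic cohort
(the acceptance suite checks exactly this).

### Curve smoothing

Per-age biweight means are smoothed by a penalized discrete cubic
smoothing spline (a second-difference penalty on the unit age grid). The
penalty weight is set from the requested 50% frequency-response wavelength
analytically, $\lambda = (2 - 2\cos(2\pi/P))^{-2}$, the standard way
dendrochronological splines are parameterized; the default cutoff is 10%
of the maximum cambial age. A modified negative exponential
$w(a) = \alpha e^{-\beta a} + \kappa$ is available as a stiffer
alternative. Curves are floored at 0.001 mm so ratio indices stay defined,
and are only defined at ages with at least one contributing ring.

### Tukey's biweight and the chronology

Per-year indices are combined with Tukey's biweight robust mean (tuning
constant $c = 9$, scale fixed at the median absolute deviation about the
median, location iterated to $10^{-9}$, at most 50 iterations). Degenerate
inputs fall back deliberately: one value is returned as-is, up to three
values return the median (for symmetric three-point sets this equals the
mean), and a zero MAD returns the median. The chronology is truncated
where the sample depth drops below 50 trees at either end (25 for
subgroup chronologies, matching the lower threshold used for plot-type and
habitat subsets); interior years below threshold are retained but flagged.
The 95% band is a percentile bootstrap across trees within each year
(1000 replicates, seeded), and the retained span is rescaled to mean
exactly 1 -- an invariant the tests assert for every chronology the
package emits.

### Signal-free iteration

Single-pass RCS absorbs part of the common signal into the age curve
whenever cambial age and calendar year are correlated across the sample.
The signal-free scheme iterates: divide the raw widths by the current
chronology, refit the curves from these signal-free measurements, then
recompute indices and the chronology from the *raw* widths against the
refit curves. Iteration stops when the largest per-year change in the
chronology falls below 0.002, with a hard cap of nine iterations (keeping
the count below ten) and a warning when the cap is hit. On a cohort with
no common signal the procedure converges immediately, and rerunning it at
the fixed point moves the chronology by less than the tolerance.

The method's value is conditional: with continuous recruitment single-pass
RCS is nearly unbiased and iteration mostly adds variance, whereas with a
narrow recruitment window (all trees of similar age, the regime in which
northern cohorts are often sampled) single-pass RCS visibly shrinks
mid-record features and the signal-free estimator recovers them. The
default synthetic cohort uses a 30-year recruitment window for exactly
this reason: it is the regime where the estimator under test has work to
do.

## Climate-growth analysis

The variable set holds monthly mean temperature and monthly precipitation
for May-August of the growth year and the previous year (sixteen monthly
variables -- the standard correlation grid) plus seasonal May-August and
October-April precipitation totals for both years, the October-April total
spanning the year boundary and assigned to the later year. Precipitation
is natural-log transformed as $\log(x + 0.1\,\mathrm{mm})$ before any
correlation; the offset keeps zero-precipitation months representable and
is applied identically in static, moving and boosted-tree analyses.

### Bootstrap significance

Significance of a correlation uses a stationary bootstrap of year pairs
(geometric block lengths, mean 5 years -- enough to respect the modest
autocorrelation of ring-width indices). The 95% interval is built on the
Fisher-z scale, where the sampling variance of a correlation is
stabilized, as $z \pm 1.96\,\kappa\,\mathrm{sd}(z^*)$. The factor
$\kappa = \big(1 - 3(1-p)/(np)\big)^{-1/2}$ (with $p$ the reciprocal mean
block length) corrects a small-sample downward bias of the block
bootstrap's variance; the bias stems from the negative bias of empirical
autocovariances entering the resampling scheme through the cross-product
series and the two mean-centerings. A plain percentile interval from the
same resampling over-rejects on white noise (about 7.7% at $n = 98$ in
simulation); the corrected interval attains close to nominal size, which
the acceptance suite verifies by Monte-Carlo at $n = 98$ and within
25-year windows. The construction still follows the "significant when the
95% interval excludes zero" rule.

### Moving windows and the low-frequency test

Moving correlations use 25-year windows stepped by one year, labelled by
their start year; each window's correlation is an ordinary Pearson
correlation of the transformed slice (the tests require exact agreement
with a slice-wise computation, at $10^{-12}$). To ask whether the
*evolution* of a correlation over time is more than chance, the
low-frequency test takes the variance of the moving-r series as its
statistic and rebuilds its null by recomputing moving correlations for
surrogate chronologies obtained by a circular block bootstrap (fixed
5-year blocks) against the fixed climate series; $p$ is the fraction of
null variances at least as large as the observed one, so a perfectly
stable moving correlation gives $p = 1$ by construction. The test refuses
fewer than 100 surrogates or fewer than 20 windows.

### Boosted regression trees

Nonlinearity and interactions are examined with gradient-boosted
regression trees: tree depth 2, learning rate 0.001, bag fraction 0.5,
tree count selected by 10-fold cross-validation up to a 30000-tree cap
(the engine is xgboost with a single thread, which keeps fits
reproducible under a seed). Relative influence is per-feature split gain,
aggregated back to the parent variable for one-hot-encoded categories and
normalized to sum to 100. Partial dependence evaluates the model over one
variable's grid with every other encoded column at its training mean;
pairwise interactions are screened with a Friedman-style H statistic on a
joint grid among the top-influence variables. One caveat the tests
document: with a pure-noise target, cross-validation keeps very few trees
and the influence of those few splits is necessarily concentrated, so the
meaningful null check is instability of the apparent winner across
replicates, not a flat influence profile.

## Isotope physiology

Carbon isotope discrimination is
$\Delta^{13}C = (\delta^{13}C_a - \delta^{13}C_{tree}) /
(1 + \delta^{13}C_{tree}/1000)$, from which
$C_i/C_a = (\Delta - a)/(b - a)$ with $a = 4.4$ permil (diffusion through
stomata) and $b = 27$ permil (carboxylation), $C_i$ follows from the
atmospheric concentration, and intrinsic water-use efficiency is
$\mathrm{iWUE} = (C_a - C_i)/1.6$. For the gas-exchange chain a fixed
offset of $-1.33$ permil is applied to cellulose $\delta^{13}C$ first
(alpha-cellulose is enriched relative to the leaf tissue for which the
$C_i/C_a$ relation was developed); the reported raw discrimination is
deliberately left unadjusted. The atmospheric reference
($\delta^{13}C_a$, $C_a$) is extended past its last measured year by
separate OLS lines fit over 1993-2002, predicting 2003-2012, with
extrapolated years flagged; period-level atmospheric values are arithmetic
means of the annual values within each period. The packaged reference
series is synthetic (generated by `generate_reference()` and labelled as
such in its provenance column); users with a published reference series
supply it as a CSV with `year`, `d13c_air`, `ca`.

Young rings discriminate more (soil-respired CO2, shade, a shorter
hydraulic path), so period contrasts are separated from the ring-age
profile with a random-forest regression of discrimination on ring age and
period (500 trees, permutation importance, seeded). Period effects are
read off the fitted surface with ring age held constant (`hold_age`,
default 100 years, near the mean age of typical isotope trees). One
practical caution established during development: evaluating at an age
outside a period's observed age support forces the forest to extrapolate
and attenuates the contrast, so recovery scenarios in the acceptance suite
evaluate at age 60, which lies inside every contrasted period's support.

## Habitat analysis

Each tree's ring-width indices are averaged over 2003-2012 and joined to
its plot's locational and structural covariates; the same BRT engine
relates recent growth to habitat. Habitat quality is classified by fixed
thresholds read from partial-dependence breakpoints: white spruce habitat
is good below 50% moss cover and 10 cm duff depth and poor above both;
black spruce habitat is good above a 15% slope and 60% moss cover and poor
below both. The published rules use strict inequalities, leaving the
boundaries undefined, so boundary values and records missing a required
field are classified `unclassified`; good and poor are mutually exclusive
by construction. Stratified chronologies (full signal-free RCS per
stratum, 25-tree threshold) are then correlated with the sixteen monthly
climate variables to produce the species-by-habitat correlation grid.

## The synthetic-data generator

The generator encodes the statistical structure the analysis assumes,
with known ground truth for every recovery test. Climate: monthly
temperature is a seasonal climatology plus AR(1) anomalies
($\phi = 0.5$, sd 1.5 degrees C) plus a linear warming trend after 1965
(0.03 degrees C/yr); monthly precipitation is lognormal around a seasonal
mean (August mean 45 mm, so the 40-80 mm response range is active). The
common signal is a decreasing sigmoid of May-August mean temperature
(midpoint 14 degrees C, steepness 1.5 per degree, floor 0.6) times a
saturating ramp of August precipitation (40-80 mm, floor 0.7), with the
previous year's responses entering at reduced weight (0.8 for
temperature, 0.3 for precipitation -- boreal conifer chronologies
correlate with the previous summer about as strongly as with the current
one, and the lagged terms give the previous-year variables of the
correlation grid something real to detect). Trees get lognormal growth
multipliers (sdlog 0.25) on a negative-exponential age trend
($\alpha e^{-0.025a} + 0.15$ mm), multiplicative lognormal ring noise
(sd 0.2), and plot-level habitat classes whose level multipliers and
temperature-sensitivity exponents are configurable (neutral by default).
A configurable fraction of trees (30%) misses the pith: their first rings
are withheld and replaced by arc metadata computed from the true geometry,
so the pith-correction path is exercised end to end. Isotope records are
elevated by a juvenile term $d\,e^{-a/18}$ (0.5 permil for black, 1.5 for
white spruce), decline over the first 50-70 rings, rise slowly afterwards
(0.25 permil per century), and carry configurable period effects plus
0.3 permil measurement noise; cellulose values are produced by inverting
the discrimination equation against the synthetic reference.

Default problem sizes: 150 trees over 150 years for the standard recovery
cohort; a `field` profile at a full campaign scale (213 + 339 trees) and
a `ci` profile (60 trees/species) for fast end-to-end runs. Recruitment
spans 1864-1894 by default (the regime where signal-free RCS matters, see
above); scenarios that need mixed-age samples -- the isotope age
adjustment, which requires a ring-age range above 50 years, and
level-shift contrasts -- extend recruitment to 1964, mirroring field
campaigns that deliberately sample young and old trees.

What the generator does *not* emulate: crossdating error and locally
absent rings, spatial autocorrelation between plots, disturbance beyond a
simple fire-year truncation, within-year (earlywood/latewood) structure,
climate regime shifts beyond the single linear trend, and any dependence
of isotope discrimination on climate. Passing recovery tests therefore
demonstrate that the estimators do what they claim under the stated
statistical structure, not that real cores are free of the field problems
the generator omits.

## Known limitations

* The signal-free iteration can fail to reach its 0.002 tolerance within
  nine iterations on strongly age-confounded cohorts; it then warns and
  returns the last iterate. The iteration cap is part of the method's
  definition here, not a tunable.
* The block-bootstrap significance correction is derived for the leading
  small-sample bias term and verified by simulation at the record lengths
  used ($n = 25$ and $n = 98$); strongly autocorrelated series (AR(1)
  coefficient well above 0.5) will still be somewhat anti-conservative.
* Random-forest period adjustment attenuates period contrasts when asked
  to evaluate outside a period's age support; choose `hold_age` inside the
  common support of the periods being compared.
* BRT relative influence under near-null signals concentrates in the few
  cross-validation-surviving trees; judge influence tables together with
  the model's explained variance.
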