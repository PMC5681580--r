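Package: borealrings
Title: Signal-Free RCS Tree-Ring Chronologies, Climate-Growth Analysis and
    Carbon-Isotope Gas-Exchange Physiology for Boreal Spruce
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building tree-ring chronologies from increment-core
    ring-width series and relating them to climate, habitat and gas-exchange
    physiology, designed around boreal black and white spruce. Reads and
    writes Tucson/RWL decadal ring-width files, applies geometric
    missing-radius (pith offset) correction and fire-year filtering, and
    detrends with multi-curve regional curve standardization (RCS) made
    signal-free by iterative removal of the common year signal. Chronologies
    use Tukey's biweight robust mean with bootstrap confidence bands.
    Climate-growth relationships are examined with static and 25-year
    moving-window correlations (stationary-bootstrap significance, a
    block-bootstrap low-frequency variance test) and boosted regression
    trees. Tree-ring alpha-cellulose delta-13C is converted to carbon
    isotope discrimination, Ci/Ca, Ci and intrinsic water-use efficiency,
    with a random-forest ring-age adjustment. Habitat analyses classify
    good and poor habitat and compare stratified chronologies. A seeded
    synthetic-data generator with known ground truth supports end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    xgboost,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
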