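Package: topospec
Title: Topographic Change and Spatial Variation in Speciation Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to link palaeo-topographic change to present-day spatial
    variation in speciation rates. Computes tip speciation rates from dated
    phylogenies (the DR / inverse equal-splits statistic), aggregates species
    ranges to range-weighted assemblage rates on an equal-area grid, derives
    elevation and temperature change layers from present and palaeo rasters
    with uplift/erosion partitioning, and fits piecewise path models whose
    component regressions use maximum-likelihood spatial simultaneous
    autoregressive (SAR) error models, with d-separation tests of missing
    paths and standardized direct/indirect/total effect decomposition.
    Includes a synthetic-world generator (birth-death trees, contiguous
    ranges, structured landscape layers with known coefficients) so the whole
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    MASS,
    methods,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
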