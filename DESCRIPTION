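Package: leafcarbon
Title: Whole-Plant Carbon-Balance Simulation of Arabidopsis Leaf Area Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An hourly whole-plant carbon-balance simulator for Arabidopsis
    thaliana that partitions net assimilated carbon among leaf area growth,
    leaf thickening, root growth and inflorescence growth across four
    developmental phases, including diel starch buffering, growth and
    maintenance respiration, and a heterotrophic seed-reserve phase.
    Partition coefficients are calibrated against sparse harvest
    measurements with a sigmoid weighted-difference objective and a built-in
    NSGA-II multi-objective optimizer, followed by hierarchical clustering
    and ranking of qualified parameter settings.  Includes a one-at-a-time
    sensitivity protocol for partition coefficients and drivers, derived
    growth metrics (specific leaf area, relative growth rates, mass ratios),
    and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
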