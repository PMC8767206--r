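Package: nichebreadth
Title: Climate Niche Breadth from Occurrence Records with Phylogenetic
    Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes discrete climate-class niche breadth per species from
    georeferenced occurrence records and a Koeppen-Geiger class raster,
    encodes breeding-system by ploidy states as non-exclusive indicator
    predictors, and fits both ordinary least-squares and phylogenetic linear
    models under Brownian motion with an additional independent error
    variance, with parametric-bootstrap intervals for the variance
    components. Includes a synthetic-data generator (Yule trees, trait
    states, patch rasters, occurrence clouds, model-based responses) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
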