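Package: cropconsensus
Title: Consensus Fusion and Design-Based Validation of Binary Cropland Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes co-registered binary land-cover rasters onto a common
    analysis grid, builds a per-pixel vote (consistency) map across products,
    sweeps consensus thresholds scored against an independent reference sample
    and census areas, and selects a refined cropland map by a
    highest-F1 / lowest-census-bias rule. Includes design-based (stratified)
    accuracy and area estimation with standard errors and confidence
    intervals, multi-source reference-sample pooling with stratified random
    sampling on vote-map strata, zonal area comparison against census tables
    (agreement R-squared and RMSE), a minimal GeoTIFF reader/writer for
    single-band integer rasters, and a fully seeded synthetic-scene generator
    (spatially autocorrelated truth, error-corrupted product maps, zones,
    census, sample pools) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
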