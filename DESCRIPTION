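Package: envgrid
Title: Harmonized Environmental Gridded Covariates for Epidemiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ingests satellite-style raster products and ground-station
    tables, harmonizes them onto aligned multi-level grids, cleans and
    reconstructs land surface temperature with an elevation lapse-rate
    model, computes vegetation and water indices and station-interpolated
    precipitation surfaces, and derives epidemiological covariates
    (growing degree days, De Martonne aridity, rainy-day counts, windowed
    variability statistics and the 19 bioclimatic variables). Includes a
    seeded synthetic-fixture generator with known ground truth, a
    plain-text raster reader/writer, a filename-convention catalog with
    query and completeness reporting, and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
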