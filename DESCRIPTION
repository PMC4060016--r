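Package: stepimpact
Title: Step-Wise Modelling of Invasive Species Impacts Across Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the landscape-scale ecological impact of an invasive
    social insect by combining three layers in a step-wise process: a
    bias-corrected presence-only (maximum-entropy-style) species distribution
    model, land-cover-specific nest density and occupancy estimated from
    field plot surveys and extrapolated nationally, and a foraging-intensity
    model based on prey-capture rates and seasonal bright-sunshine hours.
    Includes a synthetic-landscape generator (autocorrelated environmental
    fields, patchy land cover, biased occurrence sampling, zero-inflated plot
    counts, hourly sunshine stacks) with known ground truth so every pipeline
    stage can be validated without external data, plus single-band float32
    GeoTIFF input/output and a configurable end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
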