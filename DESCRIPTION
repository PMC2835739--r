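Package: picosel
Title: Selection Assay for Nitrogen-Use Gene Loss in a Seasonal
    Picophytoplankton Ecosystem Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A zero-dimensional, seasonally forced mixed-layer ecosystem model
    of picophytoplankton and larger phytoplankton competing for ammonium,
    nitrite, nitrate, phosphate and iron, with grazing, nitrification,
    remineralization and entrainment. Loss-of-function mutants for nitrate and
    nitrite assimilation are injected at a fixed per-division rate, and the
    selective disadvantage of each loss is read off as the log10 ratio of
    neutral (null) mutant to loss mutant abundance. Ships a library of named
    forcing scenarios (oligotrophic gyre, seasonal subtropics, temperate,
    iron-limited HNLC and diagnostic closed-box regimes), a seeded random
    community generator, prescribed warm/cold ecotype pairs for seasonal
    succession experiments, and ensemble and parameter-sweep drivers with
    reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
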