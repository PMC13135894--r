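Package: thermshift
Title: Thermal Performance Curves and Climate-Driven Feeding Suitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits thermal performance curves (TPCs) to temperature-rate
    observations of feeding-related traits using a registry of 22 nonlinear
    model forms with small-sample Akaike (AICc) model selection, residual
    bootstrap confidence intervals, and extraction of derived thermal
    parameters (rmax, Topt, CTmin, CTmax, Q10). Projects fitted curves over
    monthly temperature grids to a normalized Thermal Habitat Suitability
    (THS) index in [0,1], aggregates to annual means under land-sea masking,
    classifies suitability into five classes, and quantifies class-extent
    changes, range expansion, and monitoring priority between baseline and
    future climate scenarios. Includes a synthetic-data generator for trait
    observations and paired monthly temperature grids so the full pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
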