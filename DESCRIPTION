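Package: noctresp
Title: Nocturnal Decline of Plant Dark Respiration
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models, fits and simulates the temperature-independent nocturnal
    decline of plant dark respiration. Provides the closed-form respiration
    equations (Q10 and temperature-dependent Q10 temperature responses, the
    universal power-law decline of the basal rate, and their merged nocturnal
    formulations), seeded generators of synthetic respiration traces and
    meteorological forcing, the normalization/hourly-binning/aggregation
    pipeline with an SEM-weighted nonlinear power-law fit, decomposition of
    nocturnal respiration change into temperature and non-temperature control
    (apparent versus inherent Q10), model-evaluation statistics (one-to-one
    regression, standardized residuals, Taylor statistics), and a single-site
    simulator of whole-plant respiration and net primary production with and
    without the nocturnal decline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
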