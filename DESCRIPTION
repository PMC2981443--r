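Package: pterosoar
Title: Structural and Aerodynamic Flight Analysis of Giant Pterosaurs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biomechanical assessment of flight capability in giant
    pterosaurs. Implements an elliptical-beam model of long-bone midshaft
    strength (polar section modulus, cantilever failure force, relative
    failure force against avian structural scaling), a two-term glide-polar
    flight-performance model (stall, best glide, minimum sink, anaerobic
    burst climb-out range), derived wing-planform metrics with a
    size-normalised ecomorphospace projection, and mass/size rescaling
    utilities (segment-wise volumetric correction, span-mass power-law
    regression, body-density plausibility checks). Includes seeded
    generators of synthetic morphometric and planform data for validating
    every stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    cluster,
    knitr,
    rmarkdown
Config/testthat/edition: 3
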