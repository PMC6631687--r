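Package: ivivepk
Title: In Vitro-In Vivo Extrapolation of Hepatic Clearance for PET Radiotracers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting in vivo plasma clearance of positron
    emission tomography (PET) radiotracers from microsomal stability data.
    Implements the substrate-depletion half-life approach (monoexponential
    depletion fits, lipophilicity-based correction for nonspecific microsomal
    binding, physiological scaling to intrinsic clearance), the well-stirred
    liver model, and prediction-accuracy metrics (fold error, average fold
    error, root mean square error). A companion in vivo module converts raw
    per-animal plasma radioactivity measurements into decay- and
    metabolite-corrected concentration curves, fits a triexponential
    disposition model, and derives plasma clearance, volume of distribution
    and terminal half-life. Plasma free fractions are computed from
    ultrafiltration count pairs. A synthetic-data generator reproduces the
    statistical structure of a rat radiotracer study so that every pipeline
    stage can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
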