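Package: combopd
Title: Pharmacodynamic Modeling of Cisplatin-Cimetidine Combination Effects
    on Cancer Cell Viability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of the anticancer interaction between
    cisplatin and cimetidine in OCT2-negative (Huh7) and OCT2-positive
    (MDA-MB-468) cancer cell lines. Implements inhibitory Hill
    concentration-response fitting, a competitive interaction model with an
    interaction parameter (psi) and additive 3D response-surface
    classification, and a cell-level pharmacodynamic model with three signal
    transit compartments for time-course viability data. Provides nonlinear
    least-squares estimation with relative standard errors, a synthetic
    CCK-8-style viability data generator, and an end-to-end reproducible
    pipeline (simulate, fit single agents, fix, estimate psi, classify).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
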