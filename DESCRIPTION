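Package: pbrsm
Title: Plackett-Burman Screening and Response Surface Optimization for
    Fermentation Media
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage statistical optimization of fermentation media:
    Plackett-Burman fractional factorial screening with dummy-variable
    estimation of experimental error, and response surface methodology on
    rotatable central composite designs, including second-order least-squares
    fitting in coded variables, ANOVA with lack-of-fit decomposition against
    pure error from replicated center points, fit diagnostics (coefficient of
    variation, adequate precision), stationary-point and constrained-region
    optimization of the fitted quadratic surface, and seeded simulation of
    design-response datasets with known ground truth. Ships the cellulase
    production case study (a Bacillus amyloliquefaciens medium optimization)
    as plain-text fixtures so the full analysis is reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
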