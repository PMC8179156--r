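Package: tracerscreen
Title: Stable-Isotope Tracer Screening for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens aligned untargeted LC-MS feature tables from
    stable-isotope tracer feeding experiments for metabolite processing
    intermediates. Implements noise flooring and internal-standard
    normalization, a deuterium mass-shift isotopologue pair screen
    (intensity, mass-difference, co-elution and treatment-response
    criteria), a Spearman rank-correlation co-behavior screen, cross-mode
    consolidation of adduct forms, exact monoisotopic mass annotation
    against a compound library, isotope-budget arithmetic, and a seeded
    synthetic feature-table generator with planted ground truth for
    validating every screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
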