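Package: enzopt
Title: Taguchi Signal-to-Noise Optimization of Enzymatic Esterification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing enzymatic esterification (biolubricant
    synthesis) with the Taguchi method: construction and validation of the
    L9(3^4) orthogonal array, acid-value titration to fatty-acid conversion,
    larger-is-better signal-to-noise analysis with response tables and
    optimum prediction, pooled Taguchi ANOVA with percentage contributions,
    an additive linear conversion model in physical units with contour and
    parity diagnostics, a synthetic-experiment generator for parameter
    recovery studies, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
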