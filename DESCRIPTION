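Package: scaffoldlab
Title: Quantitative Characterization of Polymer-Coated Calcium-Phosphate Bone Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for polymer-coated beta-tricalcium-phosphate
    bone-substitute scaffolds: coating-efficiency and water-absorption mass
    balances with group summaries, 3-point flexure mechanics (flexural
    strength, elastic modulus from the linear load-deflection window,
    elongation at break), descriptive degradation kinetics (pH and
    conductivity time series), and a Raman spectroscopy workflow that
    detects cell-mediated hydroxyapatite mineralization on a
    calcium-phosphate core material via mineral-to-matrix peak ratios and
    an inverse-FWHM crystallinity index from Gaussian fits of the 960 cm-1
    apatite band. A synthetic-data module generates instrument-like inputs
    (spectra, load-deflection curves, mass tables, degradation series) with
    retained ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
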