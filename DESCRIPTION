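Package: lipidscreen
Title: LC-MS Lipidomics Semi-Quantitation and Dose-Response Biomarker
    Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Data-processing chain for high-resolution LC-MS lipidomics with
    deuterated internal standards: shorthand lipid-name parsing, monoisotopic
    and adduct/isotopologue m/z computation for labelled standards, extracted
    ion chromatogram integration with a retention-time drift exclusion,
    3x-blank censoring and single-point internal-standard semi-quantitation
    normalised per mg of tissue. Downstream, a dose-response biomarker screen
    (per-lipid linear trend on diet-group means with slope significance,
    R-squared and strict successive-change criteria), two-group comparison
    statistics, and relative-composition (Mol%) tools that expose the closure
    artifact that absolute concentrations avoid. Includes synthetic generators
    for concentration cohorts and chromatographic scan series, and a packaged
    transcription of a four-diet ruminant-fat feeding study's liver lipid
    table.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mzR
Config/testthat/edition: 3
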