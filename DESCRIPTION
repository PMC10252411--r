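Package: ciderdry
Title: Dryness Scales and PLS1 Prediction Models for Hard Cider
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for relating the chemical composition of hard apple cider
    to its perceived sensory dryness. Implements the rule-based marketable
    dryness scales (the IRF residual-sugar to malic-acid ratio, with and
    without pH correction, and the NYCA tannin-corrected scale), a PLS1
    calibration engine built on the NIPALS algorithm with segmented
    cross-validation, jackknife coefficient-uncertainty screening and
    Hotelling T-squared outlier flagging, a published linear dryness
    prediction equation, ordinal rating-agreement reports, and a seeded
    synthetic cider-chemistry generator for validating the pipeline against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
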