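Package: portalqa
Title: Portal Image Quality Analysis for Low-Z Target Imaging Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image-quality analysis for radiotherapy portal
    imaging with low-atomic-number target beams. Implements bar-pattern
    (square-wave) modulation transfer function analysis with critical (f50)
    and limiting (f10) spatial frequency extraction, contrast-detail scoring
    and three-band visibility classification of a QC phantom's low-contrast
    holes, and one-dimensional gamma-index comparison of depth-dose and
    lateral dose profiles under dose-difference/distance-to-agreement
    criteria. A parametric beam and detector model plus a synthetic phantom
    image renderer provide reproducible test images for two beam qualities
    (an aluminium-target diagnostic-energy-enriched beam and a conventional
    6 MV beam), together with paired measured/modelled dose-curve fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
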