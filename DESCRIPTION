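Package: hcscycle
Title: High-Content Cell-Cycle Profiling and Robust Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content proliferation screens: per-nucleus
    DNA-content normalization anchored at the 2N control peak, five-bin cell-cycle
    classification (sub-G1, 2N, S, 4N, >4N), robust constrained four-parameter
    logistic dose-response fitting with Tukey-biweight loss and validity gating,
    and comparison of direct cell counting against bulk proxy readouts (ATP
    luminescence, MTS absorbance, DNA fluorescence, total mitochondrial mass).
    Includes a mechanism-of-action-aware synthetic plate simulator and a nuclei
    image renderer/segmenter so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
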