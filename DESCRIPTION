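Package: nmjquant
Title: Quantification of Fluorescence Micrographs from Neuromuscular Cocultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image quantification for fluorescence micrographs of neuromuscular
    coculture experiments: nucleus detection and nucleus-anchored marker
    positivity classification, the elongation index (a morphological-opening
    residual statistic for spindle-shaped cells with thin processes),
    acetylcholine-receptor cluster morphometry with myotube-area
    normalization, and myotube size-class and coverage analysis. Includes a
    seeded synthetic-micrograph generator with ground truth so every stage of
    the pipeline can be validated without original microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    tibble,
    dplyr,
    readr,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
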