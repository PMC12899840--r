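Package: phenocur
Title: Phenotypes from Concurrent Plant Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts unidimensional phenotypes from concurrent plant imaging:
    temporal change-mask descriptors (Change+/-, NChange+/-, MaxChange+/-,
    Dispersion+) from time-ordered binary masks, true aspect ratios
    (TARmax, TARmin, TWR) from same-time multi-view silhouettes, and
    intermodal correlation and mutual information between visible, infrared
    and fluorescence images. Includes the plant-level aggregation and Welch
    two-sample comparison protocol used for treatment contrasts, a synthetic
    scene generator with planted ground truth for every phenotype, and a
    command-line interface over manifest-indexed PNG datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    EBImage,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
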