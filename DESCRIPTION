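Package: coccoxrf
Title: Synchrotron Micro-XRF Elemental Map Analysis of Single Coccoliths
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification and analysis of per-pixel X-ray fluorescence
    elemental maps of single coccoliths. Implements standard-calibrated
    spectrum fitting (nonnegative least squares over Gaussian line
    templates), calcite masking on the Ca map, molar i/Ca ratio maps,
    transect profiles with Ca concentration bands, tube/rim/margin region
    statistics, partition coefficients between calcite and culture
    solution, and a correlation-based classifier that labels each element
    as lattice-incorporated, surface-deposited, a localized contaminant,
    or absent. A ground-truthed synthetic coccolith simulator (geometry,
    element fields, raw spectra with Poisson counting noise) makes the
    whole pipeline testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    pracma,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
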