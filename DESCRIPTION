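Package: ramanlipids
Title: Ratiometric Confocal Raman Analysis of Microalgal Lipids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for in situ quantitation of microalgal lipids from
    confocal Raman spectra. Implements the ratiometric I1650/I1440 workflow:
    synthetic single-cell spectra and hyperspectral scenes with pigment and
    fluorescence interference, moving-average background subtraction,
    protein-contamination and photobleach quality control, Lorentzian
    multi-peak deconvolution of the CH2-bending, C=C-stretch and olefinic
    =C-H bands, linear and four-parameter-logistic calibration against
    fatty-acid standards (double-bond count, chain-normalized unsaturation,
    melting point), coarse-to-fine lipid-droplet localization in
    hyperspectral maps, and single-cell population classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
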