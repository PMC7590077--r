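Package: nirscreen
Title: Multistage Chemometric Screening for Cocaine in Short-Range NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for presumptive detection of cocaine in powdered street
    samples from 740-1070 nm handheld near-infrared reflectance spectra.
    Implements standard normal variate and Savitzky-Golay derivative
    preprocessing with region-of-interest selection, an abstaining dual
    k-nearest-neighbour spectral matcher (Euclidean distance and Pearson
    correlation with acceptance thresholds), a PCA-prescaled neural-network
    salt-form classifier gated to HCl/base calls, per-form bagged regression
    trees for concentration, and the decision hierarchy that fuses the
    submodels into per-scan and majority-voted per-sample verdicts.
    Includes leave-one-sample-out and grouped cross-validation, confusion
    and concentration-fit reporting, threshold sweep curves, and a seeded
    synthetic-spectrum simulator of multi-scanner replicate scans of powder
    mixtures for testing and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
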