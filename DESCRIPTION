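Package: bifcros
Title: Simulation and Quantification for Low-Background Fluorescence
    Repressor Operator Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing hybrid OL1/UAS operator arrays by
    simulated hierarchical type-IIS assembly, modelling the equilibrium
    titration of a split fluorescent reporter pool against array binding
    sites, generating seeded synthetic 16-bit fluorescence microscopy
    images of rod-shaped bacteria with ground truth, segmenting cells and
    extracting raw pixel intensities, computing per-cell
    signal-to-background statistics with intensity and ratio filters, and
    running population-level analyses (area binning, control-strain
    background subtraction, signal-versus-background regression, and
    copy-number fold-change estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
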