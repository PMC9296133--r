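Package: nedyn
Title: Quantification of Nuclear Envelope Formation and Growth in Early Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for nuclear formation and growth in early
    C. elegans embryos from fluorescence time-lapse and electron-tomogram
    traces. Quantifies nucleocytoplasmic import from two-channel image stacks
    (background-corrected nuclear/cytoplasmic ratio scaled by nuclear area,
    onset detection, normalized-difference curves), fits single-exponential
    FRAP recovery to estimate mobile fractions and half-times, integrates
    traced nuclear contours into volumes with a sphericity check against the
    widest-slice theoretical volume, extracts nuclear-rim line-scan profiles,
    classifies sub-100 nm membrane gaps as nascent nuclear pore complex holes
    and computes their per-area densities, and summarizes embryonic-lethality
    and qPCR delta-delta-Ct tables. Includes synthetic-data generators with
    closed-form ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    jsonlite,
    minpack.lm,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
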