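Package: hrgcms
Title: High-Resolution GC-MS Metabolite Annotation and Twin-Platform
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating derivatized metabolites in gas
    chromatography-mass spectrometry (GC-MS) data when accurate-mass
    (Orbitrap-class) spectra are available, and for comparing the outcome
    against a unit-mass instrument. Implements elemental formula
    decomposition under chemical plausibility rules (ring-and-double-bond
    equivalents, SENIOR condition, element-ratio ranges), trimethylsilyl
    and methoxime derivatization arithmetic, Kovats retention indices,
    NIST-style MSP spectral file input/output, dot-product spectral
    library matching, high-resolution filtering of library hits by
    fragment sum-formula verification, methane chemical-ionization
    adduct-series molecular-ion detection, quality-control based signal
    drift correction and feature filtering, volcano statistics with false
    discovery rate control, principal component analysis, and a
    ground-truthed synthetic generator of paired high-resolution and
    unit-mass experiments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
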