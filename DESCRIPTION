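Package: cellsizer
Title: Cell-Size Homeostasis Analysis and Size-Variability Mutant Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cell-size homeostasis in rod-shaped cells
    such as fission yeast. Provides a stochastic lineage simulator for
    sizer, adder and timer division control with frame-sampled time-lapse
    recording; dispersion statistics (coefficient of variation, quartile
    coefficient of variation, skewness) with the Feltz-Miller asymptotic
    chi-square test for equality of coefficients of variation and a
    permutation counterpart; the birth-length versus extension (BL/E)
    regression with 0.5 um birth-length cohorting and sizer/adder/timer
    classification; a two-gate screen for mutants with increased size
    variability at division; and quantification of multinucleate division
    synchrony and per-nucleus fluorescence intensity variability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
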