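Package: ebftools
Title: Electron Backscatter Dose Enhancement at Internal Lead Shielding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the dose enhancement produced by electrons backscattered
    from internal lead (Pb) shielding in clinical electron beams. Implements
    an empirical two-exponential model of the electron backscatter factor
    (EBF) at a tissue-lead interface as a function of the mean electron
    energy, a log-linear model of the exponential decay of the enhancement
    with upstream distance, and the staged least-squares procedure that
    estimates the model coefficients from paired central-axis depth-dose
    curves scored with and without a saturation-thickness Pb slab. Includes
    depth-dose input/output and normalization, beam-quality characterisation
    (R50, practical range, mean surface energy), perturbation of a
    percentage depth-dose curve by a Pb slab, a seeded synthetic generator
    emulating Monte Carlo scored depth-dose curves, comparison utilities
    against legacy backscatter equations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
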