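Package: degronscreen
Title: Quantitative Analysis of Yeast Degron Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for degron-library screens in budding yeast
    built around a Ura3-HA reporter readout. Computes peptide sequence
    features (Kyte-Doolittle GRAVY hydropathy, hydrophobic-stretch length,
    fusion-frame translation of cloned inserts), normalizes colony-size
    plate data to on-plate control wells and calls growth differences
    between E3-ligase mutants and wild type with Mann-Whitney tests, fits
    first-order exponential decay to cycloheximide-chase time courses to
    estimate protein half-lives with extra-sum-of-squares F-tests for curve
    comparison, and integrates growth and kinetics into per-degron
    E3-dependence calls. A synthetic-screen generator with known ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    stats,
    Biostrings,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
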