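Package: nitroredscope
Title: Quantitative Analysis of Nitroreductase-Mediated Nitroaromatic Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the quantitative analyses used to
    characterise flavin-dependent nitroreductases and their nitroaromatic
    substrates: calibrated one-electron reduction potentials from
    quantum-chemical free energies via an isodesmic thermodynamic cycle,
    Michaelis-Menten and Hammett substituent-effect kinetic fitting,
    dye-referenced equilibrium redox titration (log-log Nernst analysis of
    two-electron couples), molecular-formula arithmetic for nitroso,
    hydroxylamine and amine reduction products with LC-MS m/z prediction, and
    solvent-accessible surface area, buried dimer-interface area and CPK
    molecular volume from atomic coordinates. Seeded synthetic-data
    generators emulate each data type so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
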