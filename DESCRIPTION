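Package: rrnasip
Title: High-Sensitivity rRNA Stable Isotope Probing of Pollutant Degraders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of high-sensitivity rRNA stable isotope
    probing (SIP) experiments on activated-sludge communities degrading a
    13C-labeled substrate. Provides isotope conversions (delta-13C to atom
    percent, bicarbonate equilibrium fractionation) and a 13C tracer mass
    balance over closed-vial incubations; a seeded generator of
    density-gradient amplicon libraries with known incorporators; detection
    of 13C-incorporating taxa by fraction-matched replicated t-tests on
    relative abundances; per-taxon rRNA expression estimation from qPCR
    totals and amplicon fractions with trajectory classification; and
    long-term bioreactor monitoring summaries (removal efficiency,
    MLSS-scaled abundances, alpha diversity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
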