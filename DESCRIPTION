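Package: acetoledger
Title: Bioenergetic Ledgers and Expression Screening for Acetogenic
    Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis of acetogenic (Wood-Ljungdahl) metabolism
    in the thermophilic acetogen Moorella thermoacetica. Provides redox
    couple thermodynamics with Nernst corrections for hydrogen partial
    pressure, exact (rational-arithmetic) stoichiometric ledgers of
    electron-carrier balancing with chemiosmotic proton and ATP accounting
    for growth on H2 + CO2 (high and low partial pressure) or CO, a
    two-condition negative-binomial differential-expression stage with
    Benjamini-Hochberg correction, photometric enzyme-activity and
    growth-curve calculations, and seeded synthetic-data generators for
    every input the pipeline reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
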