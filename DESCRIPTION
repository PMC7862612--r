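Package: leukotox
Title: Quantitative Screening for Chemical Immunotoxicity in Fish Leukocyte Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for plate-based in vitro
    immunotoxicity screening with fish head-kidney leukocytes. Provides a
    factorial linear model with per-fish base levels, LPS stimulation, exposure
    duration and chemical concentration effects plus their interactions, Wald
    tests of linear coefficient combinations, and lowest-observed-effect
    concentration (LOEC) extraction; relative qPCR quantification of cytokine
    transcripts by the 2^-ddCt method; EC20 cytotoxicity estimation from
    calcein/DAPI viability data; an equilibrium-partitioning mass-balance
    prediction of baseline-toxicity IC10 from a critical membrane
    concentration; and toxic-ratio / specificity-ratio classification of
    chemical effects. A synthetic-data generator reproduces the factorial
    structure the analysis assumes so the whole pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
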