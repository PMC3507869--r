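Package: epimsap
Title: Simulation and Screening of Chemically Hypomethylated Plant
    Populations from MSAP Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytical pipeline for forward screens of 5-azacytidine
    (5-AzaC) hypomethylated plant populations. Simulates paired
    methylation-sensitive amplified polymorphism (MSAP) band matrices for
    the HpaII/MspI isoschizomer pair under stochastic demethylation,
    computes AMOVA variance components with PhiPT permutation tests to
    flag effectively hypomethylated lines, performs principal coordinate
    analysis of epigenetic distances, fits a constrained logistic
    dose-response curve (upper asymptote fixed at 100%) with lower
    asymptote and lack-of-fit F-tests, builds epimutagenesis population
    pedigrees, and decomposes sib-line trait variance with
    cluster-robust treatment contrasts and fatty-acid correlation
    analysis. Every stage runs on synthetic data generated by the
    package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ggplot2
Config/testthat/edition: 3
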