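Package: kdrtox
Title: Pyrethroid Resistance Analysis: Probit Bioassays, Sodium Channel
    Modification and kdr Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising pyrethroid resistance in mosquito
    populations: probit concentration-mortality analysis with Fieller
    confidence limits and resistance ratios, synergist bioassay comparison by
    one-way ANOVA with Scheffe post hoc contrasts, quantification of
    pyrethroid-modified sodium channels from two-electrode voltage-clamp tail
    currents (the M statistic) with Hill dose-response fitting and EC50
    fold-shift estimation, and kdr codon genotyping with allele-frequency and
    population-screening summaries. A synthetic-data module simulates
    binomial mortality under a probit model, sodium-current traces under a
    pulse-train protocol with a known modified-channel fraction, and strain
    coding-sequence pairs and diploid amplicon panels with planted variants,
    so every analysis stage has a known-truth recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
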