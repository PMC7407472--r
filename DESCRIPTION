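Package: tunemut
Title: Analysis of Tunable-Mutation-Rate Bacterial Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for evolution experiments in bacteria whose point
    mutation rate is set by inducible mismatch repair. Estimates mutation
    rates from rifampicin fluctuation assays via the Luria-Delbruck
    distribution and the Ma-Sandri-Sarkar maximum-likelihood method with
    Stewart confidence intervals; fits Hill-plus-shift dose-response curves
    of expression and mutation rate against inducer concentration; extracts
    growth phenotypes (early exponential rate, time to leave exponential
    phase, saturating OD600) from daily plate-reader traces; parses breseq
    GenomeDiff mutation calls, applies ancestral/shared-well/frequency
    filters and builds cumulative-SNP curves; and tests genes for mutation
    clustering with a Monte-Carlo genome-wide window scan statistic.
    Seeded synthetic-data generators emulate every input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
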