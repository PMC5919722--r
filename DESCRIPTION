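Package: dosevar
Title: Gene-Dosage Expression Variability from Replicated RNA-Seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organism-level analysis of gene expression variability under
    reduced gene dose. Implements the replicate-pair variability statistic
    delta = 2|FPKM1 - FPKM2|/(FPKM1 + FPKM2) and its group-wise rank-sum
    comparisons, intergenic-background expression cutoffs, per-gene dose
    assignment from deficiency (Df) deletion intervals, dosage-response
    scoring against the twofold-reduction baseline, chromatin-occupancy
    stratified coefficient-of-variation comparisons, an exact Gillespie
    simulation of the ON-OFF (telegraph) transcription model with
    population averaging, and a synthetic-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
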