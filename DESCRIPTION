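Package: msrisksim
Title: Multi-SNP Genetic Risk Model Simulation for Multiple Sclerosis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayes-theorem polygenic risk modelling for multiple sclerosis
    (MS). Builds per-genotype likelihood ratios from risk-allele frequencies
    and per-allele odds ratios under Hardy-Weinberg equilibrium, simulates
    genotypes and disease status for large populations, and estimates the
    discriminative accuracy (area under the ROC curve) of risk panels of 6,
    24 and 53 susceptibility variants. Includes an inverse search for the
    odds ratios hypothetical variants must carry to reach target AUCs, a
    synthetic case-control cohort generator emulating a 591-case/600-control
    study, and a weighted risk-allele-score analysis pipeline (per-SNP
    association, risk-allele-count bins versus the a-priori cohort risk,
    cohort AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
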