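Package: bafnorm
Title: Tumor-Normal Normalization of Allele B Fractions and Allelic
    Imbalance Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-pair normalization of tumor allele B fractions (BAF)
    against a matched normal for SNP genotyping arrays (the TumorBoost
    method). Includes a naive kernel-density genotyper for the normal
    sample, decrease-in-heterozygosity (DH) statistics, a normal
    contamination (tumor purity) model for true allele fractions and DH,
    a change-point detectability evaluation framework (bootstrap
    t-statistics and ROC analysis on binned DH tracks), and a synthetic
    paired tumor-normal signal generator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
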