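Package: eqtlatlas
Title: Species-Wide Expression QTL Mapping and Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping expression quantitative trait loci (eQTL)
    across panels of inbred wild strains: expression quality control and
    median-of-ratios normalization, kinship-aware linear mixed-model
    association scans (EMMA-style REML with population-parameters
    previously determined), eigen-decomposition and Bonferroni
    significance thresholds with permutation-calibrated false discovery
    rates, local/distant eQTL classification, distant-eQTL hotspot
    detection by Poisson binning on the genetic map, broad- and
    narrow-sense heritability, fine-mapping candidate filters, and
    mediation analysis connecting genotype, transcript expression, and
    organism-level traits. A synthetic-data generator with known ground
    truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
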