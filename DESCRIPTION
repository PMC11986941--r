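Package: targetmr
Title: Drug-Target Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for two-sample drug-target Mendelian
    randomization. Constructs cis genetic instruments for LDL-C-lowering
    drug targets (HMGCR, PCSK9, NPC1L1) from GWAS summary statistics
    (gene-window filter, significance and minor-allele-frequency filters,
    greedy LD clumping, F-statistic screen, confounder-trait screen),
    harmonizes exposure and outcome effects to a shared effect allele,
    and estimates causal effects on binary outcomes with inverse-variance
    weighting, MR-Egger, the weighted median, and mode-based estimators.
    Sensitivity diagnostics include Cochran's Q, the Egger intercept test,
    MR-PRESSO outlier detection and correction, and leave-one-out
    analysis, with an automatic stricter-LD rerun when heterogeneity or
    pleiotropy is detected. A seeded synthetic-data module generates
    two-sample summary statistics with known causal effect, pleiotropy
    and LD structure so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
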