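Package: tp53pancan
Title: Pan-Cancer Transcriptome Analysis of TP53 Mutation Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pan-cancer analysis of TP53 mutations in
    tumor cohorts: rule-based classification of tumors into TP53-mutant and
    wildtype and of variants into gain-of-function, loss-of-function,
    dominant-negative and VUS classes; mutation hotspot recurrence screening
    with exact Clopper-Pearson prevalence intervals and cross-cancer-type
    homogeneity tests; fixed-sample-size Wilcoxon differential expression
    between mutation classes and against wildtype; pan-cancer consensus
    signature construction by Fisher's method with direction voting and
    Manhattan/average-linkage bi-clustering; gene-set over-representation with
    an enrichment fold-change statistic; and association of tumor mutational
    burden and immune-cell abundances with TP53 status across cancer subtypes.
    Includes a synthetic cohort generator with planted, recoverable structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
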