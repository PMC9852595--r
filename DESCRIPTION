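Package: rsclassify
Title: Methylation and Expression Classifiers for Richter Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to separate CLL-derived from DLBCL-like Richter syndrome
    (RS) using multi-omics classifiers. Implements a DNA-methylation linear
    predictor score (LPS) that weights beta-values by moderated t-statistics
    and assigns subgroup labels through Gaussian posterior probabilities, a
    gene-expression linear classifier score (LCS) built from a +/-1 weighted
    gene signature, and a methylome-transcriptome correlation integrome that
    nominates methylation-regulated promoter regions. A synthetic cohort
    generator reproduces the statistical structure of methylation-array and
    RNA-seq data (bimodal beta-values, planted differential CpGs, negative
    binomial counts, promoter-expression coupling) so every stage can be
    exercised and validated without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    edgeR,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
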