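Package: traitnet
Title: Correlation-Based Trait Network Analysis for Replicated Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds correlation-based networks from replicated metabolite and
    enzyme profiles measured on inbred line panels. Provides internal-standard
    normalization and plate standardization, EM-PCA imputation of missing
    values, per-feature variance components and broad-sense heritability by
    REML, best linear unbiased prediction (BLUP) of line effects, Spearman
    correlation with a Benjamini-Hochberg p-value cutoff and a
    stability-calibrated correlation threshold, walktrap community detection
    with a Wilcoxon signed-rank community-significance test and merging of
    non-significant communities, permutation-tested node degree and
    betweenness statistics, and Pearson shared-variance edge validation. A
    seeded synthetic-panel generator with planted heritabilities and
    correlation-block structure supports end-to-end validation.
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
    igraph,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
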