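Package: qtcgwas
Title: Multi-Marker Genome-Wide Association via Hierarchical Testing of
    Marker Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association without population-structure correction.
    Markers are clustered genome-wide by their pairwise correlations and the
    resulting hierarchy of clusters is tested top-down for association with a
    phenotype using repeated sample splitting: LASSO screening on one random
    half of the individuals and hierarchical ANOVA testing on the other half,
    with p-value aggregation across splits and family-wise error control. The
    smallest significant clusters (quantitative trait clusters, QTCs) are
    reported together with per-marker selection frequencies. Includes readers
    and writers for common genotype formats (VCF, PLINK1, delimited tables),
    simulators for structured (island-model) and biparental recombinant
    inbred line populations with calibrated-heritability phenotypes, and
    evaluation utilities (truth matching, explained variance, genomic
    relationship matrix, population-structure involvement, power curves).
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
    glmnet,
    jsonlite,
    parallel,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
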