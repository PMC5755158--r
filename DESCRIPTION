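Package: herdqg
Title: Enterotypes and Quantitative Genetics of Swine Fecal Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal analysis of swine fecal
    microbiota as heritable phenotypes. Covers OTU-table processing
    (filtering, rarefaction, taxonomic aggregation, log-centred transforms,
    Good's coverage, Kruskal-Wallis screening, PCA of composition),
    enterotype discovery (Jensen-Shannon divergence, partitioning around
    medoids, Calinski-Harabasz and silhouette cluster-number selection,
    LDA effect sizes, enterotype transitions), alpha-diversity phenotyping
    (Shannon index, OTU richness, contemporary-group pre-adjustment), and
    pedigree-based quantitative genetics (numerator relationship matrix,
    univariate and bivariate AI-REML variance components, heritability,
    genetic and phenotypic correlations, likelihood-ratio model comparison).
    A synthetic-herd generator emulates the paternal half-sib study design
    so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    vegan,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
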