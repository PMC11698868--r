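Package: alphadiv
Title: Alpha-Diversity Metric Benchmarking for Microbial Communities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes nineteen within-sample (alpha) diversity metrics for
    ASV/OTU count data, organised into four complementary categories
    (richness, dominance, information, phylogenetics), and provides the
    machinery to compare them: a synthetic community generator with exact
    control over richness, singletons, doubletons, abundance distribution
    and top-two dominance ratio; min-max normalisation; within-category
    Pearson/Spearman correlation; regressions of dominance metrics on
    Berger-Parker; LOESS fits; Kruskal-Wallis group tests; and a
    recommended reporting panel drawing one metric from each category.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ape,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Sequencing, Software
RoxygenNote: 7.3.3
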