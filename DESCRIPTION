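Package: amplibench
Title: Benchmarking 16S rRNA Amplicon Regions, Classifiers and Reference
    Databases for Species-Level Microbiota Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to evaluate how the choice of 16S rRNA gene region,
    taxonomic classification method and reference database affects
    species-level resolution of amplicon microbiome data, with an emphasis
    on the vaginal microbiota. Implements in-silico PCR with a built-in
    panel of degenerate primer sets covering the V1-V9 hypervariable
    regions, a k-mer multinomial naive Bayes classifier with bootstrap
    confidence and a top-hit alignment consensus classifier, per-species
    accuracy scoring across (method, database, region) pipelines, a
    species-to-best-database combination rule that merges complementary
    reference databases, community-profile comparison (Bray-Curtis,
    Euclidean, Jaccard and Kulczynski dissimilarities with principal
    coordinates analysis), confusion-matrix concordance metrics including
    Cohen's kappa, and a fully deterministic synthetic-data generator so
    the whole pipeline can be exercised without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
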