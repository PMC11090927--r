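Package: granulaR
Title: Temporal Diversity and Co-Occurrence Network Analysis for
    Parallel Bioreactor Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of amplicon sequence variant (ASV) time series from
    parallel wastewater-treatment bioreactors, such as aerobic granular
    sludge (AGS) and conventional activated sludge (CAS) systems sampled
    monthly over one to two years. Provides consensus merging of count
    tables from two bioinformatic pipelines, rarefaction by subsampling
    without replacement, Hill-number alpha diversity and pairwise
    Hill-framework dissimilarity with principal coordinate ordination,
    succession statistics (rate of change, moving-window time-gap
    dissimilarity curves for periodicity detection, same-day cross-reactor
    comparisons), consensus co-occurrence networks combining SparCC-type
    compositional correlations (permutation p-values) with Spearman
    correlations (Benjamini-Hochberg FDR), greedy modularity module
    detection with major-module trajectories, and functional-guild
    summaries (AOB, NOB, PAO, GAO) with temperature correlations and
    paired reactor tests. A seeded synthetic community generator with
    planted seasonal and trend modules supplies ground truth for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    vegan,
    jsonlite,
    withr
Suggests:
    biomformat,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, TimeCourse, Network, Software
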