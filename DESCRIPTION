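Package: wgbsdmr
Title: Differential Methylation and Co-Methylation Networks for
    Whole-Genome Bisulfite Sequencing Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-group differential DNA methylation analysis from
    CpG read-count tables: smoothed beta-binomial Wald tests with
    group-specific dispersion shrinkage, aggregation of significant CpGs
    into differentially methylated regions, direction-bias and
    interval-overlap permutation statistics, proximity-based gene annotation
    with Fisher enrichment, window-level co-methylation networks (biweight
    midcorrelation, soft-threshold adjacency, topological overlap, module
    eigenvectors, module-trait statistics), phenotype summaries with
    family-controlled group comparisons, and a seedable synthetic
    bisulfite-count generator with planted ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
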