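Package: poolConverge
Title: Pooled-DNA Genome-Wide Association by Convergent Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Nontemplate genome-wide association analysis for pooled
    case/control DNA hybridized to genotyping arrays. Estimates per-SNP
    allele-frequency proxies (arctan of A/B hybridization intensity
    ratios) from replicate pooled arrays, tests case-vs-control
    differences per SNP with pool-level t statistics, and identifies
    genes supported by clusters of nominally significant SNPs that
    converge across two independent samples ("converge then cluster"
    and "cluster then converge"). Significance is assigned empirically
    through Monte Carlo resampling of pseudopositive SNPs from the real
    map and through phenotype-label permutation. Includes power and
    stratification controls and a synthetic-data generator that
    emulates the pooled design (replicate-array noise, binomial pool
    composition, LD-like blocks of planted effects) so the whole
    pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: GenomeWideAssociation, SNP, Genetics, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
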