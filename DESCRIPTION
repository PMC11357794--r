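Package: poolstats
Title: Population Genetic Statistics for Pool Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators of nucleotide diversity (theta-pi), Watterson's
    theta, Tajima's D, and pairwise FST (Nei, Hudson, and the PoPoolation2
    "Kofler" and "Karlsson" variants) for pooled sequencing (Pool-seq)
    allele-count data.  The estimators correct for the two levels of
    sampling noise inherent to Pool-seq: the finite number of haploid
    genome copies in the pool, and the finite number of sequencing reads
    covering each site.  The package parses sync (PoPoolation2) and
    samtools (m)pileup files as well as simple allele-frequency tables,
    applies a configurable cascade of region, mask, and numerical quality
    filters, assembles the resulting per-position counts into six kinds of
    genomic windows, and averages window sums under six denominator
    policies.  A built-in two-stage binomial sampling simulator generates
    Pool-seq datasets with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, Genetics, Sequencing, Software
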