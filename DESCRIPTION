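Package: sweepscan
Title: Two-Population Selection-Signature Scanning from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality control, population-structure inference and sliding-window
    selection-signature scanning for two-population diploid SNP data.
    Implements per-site F_ST from population allele frequencies, windowed
    nucleotide diversity with the log2 diversity ratio between populations,
    percentile-threshold candidate windows and their intersection, interval
    overlap gene annotation and hypergeometric gene-set enrichment, together
    with a Balding-Nichols two-population genotype simulator that injects
    selective sweeps, missingness and Hardy-Weinberg violations with recorded
    ground truth. Population structure is summarised by PCA on a
    variance-standardized relationship matrix, a neighbor-joining tree from
    allele-sharing distances, and ancestry proportions from masked
    nonnegative matrix factorization with cross-entropy model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    ggplot2
Config/testthat/edition: 3
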