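Package: hdrscan
Title: Windowed Diversity Scans and High-Diversity Region Discovery from
    AllSites VCFs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Missing-data-aware estimation of nucleotide diversity (pi),
    between-population divergence (dxy) and Weir-Cockerham FST in
    nonoverlapping genomic windows from AllSites VCFs (variant plus invariant
    sites), joint-percentile calling of high-diversity regions (low FST, high
    pi in both populations), repeat and gene annotation of the called regions,
    hierarchy-aware GO term overrepresentation (classic Fisher and elim), and
    haplotype-resolved coding-sequence diversity for copy-number-variable gene
    clusters. Includes seed-deterministic simulators for two-population split
    coalescent data and for the collapsed-paralog (CNV cross-mapping) artifact
    that inflates short-read heterozygosity, with closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
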