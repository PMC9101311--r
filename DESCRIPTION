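Package: microvarsig
Title: Genomic Variation Signatures in Gut Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for analysing within-species genomic variation in gut
    metagenomes: reference-genome dereplication by a marker-gene median-identity
    proxy for average nucleotide identity, variant classification and filtering,
    twelve-type substitution spectra with transition/transversion shift tests,
    per-gene SNP density with paired Wilcoxon signed-rank testing, RPKM-like
    relative gene abundance, and tree-free NG86-style Dn/Ds per gene family with
    one-sided Fisher enrichment under Benjamini-Hochberg FDR control. Includes a
    synthetic-data generator that plants known substitution spectra, genome
    clusters, filter violations and selection pressures so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    optparse
Config/testthat/edition: 3
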