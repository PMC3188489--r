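Package: frankiatx
Title: Repeat-Aware Transcriptome Analysis for IS-Element-Laden Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a bacterial RNA-seq
    analysis workflow for genomes dense in near-identical insertion-sequence
    (IS) paralogs, modelled on the actinobacterium Frankia sp. CcI3. Provides
    a synthetic-data generator emulating a repeat-laden genome with heavy
    rRNA/tRNA carry-over and spiked variants; a seed-and-extend read mapper
    that enumerates candidate sites, discards reads above an ambiguity cap and
    places best-hit ties at random; RPKM quantification with non-coding RNA
    excluded from the denominator; two-proportion (Kal) z-test differential
    expression with signed fold-change reporting; log-scale median-centred
    heat-map clustering into expression groups; a four-criterion pileup SNP
    filter cascade with synonymous/non-synonymous codon annotation and
    multi-sample intersection; transposase density and deletion-window
    chi-square enrichment; and Pfaffl efficiency-corrected RT-qPCR relative
    quantification against a reference gene.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    graphics,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer
Config/testthat/edition: 3
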