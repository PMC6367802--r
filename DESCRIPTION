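Package: cypminer
Title: Phylogenomic Mining of Plant Cytochrome P450 Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide characterization of plant cytochrome P450 (CYP)
    multigene families: signature-motif based family mining with length
    filters, percent-identity and conservation statistics, neighbour-joining
    phylogenies with bootstrap support, intron maps with conserved
    insertion-site calling and gain/loss matrices, promoter motif scanning
    with exact binomial over-representation tests against the genome
    background, and FPKM/qPCR expression profiling.  Includes a fully
    seeded synthetic-data layer (genomes, gene models, proteins, promoters,
    alignments, expression tables) with ground-truth sidecars so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
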