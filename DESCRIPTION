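Package: hgcminer
Title: Mining hgcAB Mercury-Methylation Marker Genes from Assembled Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises hgcA/hgcB mercury-methylation marker
    genes in predicted-protein catalogs from assembled metagenomes. Provides a
    position-specific log-odds screen (or ingestion of external profile-HMM
    search tables), degenerate amino-acid motif verification, contig-aware
    locus classification into paired hgcAB clusters and lone hgcA/hgcB genes,
    redox-stratified relative abundance with filter-fraction enrichment and
    rarefaction curves, and distance-based neighbor-joining placement against
    a labelled reference set for taxonomic assignment. A synthetic survey
    generator emulates a brackish water-column metagenome survey so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomeInfoDb,
    optparse
Config/testthat/edition: 3
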