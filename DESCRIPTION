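Package: circnet
Title: Back-Splice circRNA Calling and ceRNA Network Inference from Split Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering competing-endogenous-RNA (ceRNA)
    networks from bulk RNA-seq of paired two-group designs. Calls circRNA
    back-splice junctions from chimeric split alignments (same chromosome,
    <= 1 Mb separation, same strand, reversed genomic order), scores donor and
    acceptor splice-site strength with a position-weight-matrix model over
    MaxEntScan-style windows, quantifies junction-spanning reads under a
    minimum-overhang rule, screens each RNA class for differential expression
    at |log2 fold change| > 2 and p < 0.01, gates candidate ceRNA-mRNA pairs
    by Pearson co-expression (r > 0.9, BH-adjusted p < 0.1), assembles
    direction-stratified circRNA/lncRNA-miRNA-mRNA networks, and tests network
    gene sets by hypergeometric over-representation. Includes a synthetic-data
    generator with planted ground truth (genome, back-splice read evidence,
    expression matrices, miRNA seed-match target tables) for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    fgsea,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
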