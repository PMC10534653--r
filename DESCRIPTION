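Package: aptaselex
Title: SELEX Round Enrichment Analysis for Aptamer Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of high-throughput sequencing data from SELEX
    (Systematic Evolution of Ligands by Exponential Enrichment) aptamer
    selections. Converts per-round FASTQ files into counted variable-region
    pools (constant-arm trimming, mean-quality and length filtering), groups
    sequences into abundance-ranked clusters at a 90 percent identity threshold,
    computes per-round enrichment statistics (unique/enriched read fractions,
    read-count bins, positional nucleotide frequencies, richness, Shannon and
    inverse Simpson diversity), tracks clusters across selection rounds by
    global alignment with stable lineage identifiers, builds the round-to-round
    common-cluster network, ranks final-round candidates by reads per million,
    and implements qPCR quantification (standard-curve interpolation, relative
    enrichment, delta-delta-Ct fold change). Includes a SELEX simulator that
    generates per-round FASTQ data with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
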