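Package: hgtphylo
Title: Phylogenetic Detection of Candidate Horizontal Gene Transfers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput screening and phylogenetic confirmation of
    horizontal gene transfer (HGT) candidates in sequenced genomes. Computes
    similarity-based screening metrics from tabular BLAST/DIAMOND results
    annotated with NCBI-style taxonomy (Alien Index, HGT index, outg_pct, and
    the contamination-aware Aggregate Hit Support), groups candidate queries
    by shared database hits, orchestrates alignment and gene-tree inference,
    classifies each gene tree by tagging the query's sister and ancestral
    sister branches with Donor/Ingroup affiliations, and provides downstream
    origin classification, constrained-topology evaluation, and a genomic
    neighborhood score that separates genuine HGT insertions from assembly
    contamination. Includes a synthetic-data module that generates planted
    taxonomies, hit tables, gene trees and annotated genomes for end-to-end
    validation against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    igraph,
    yaml,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
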