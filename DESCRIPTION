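Package: hckmer
Title: Reference-Free Single-Microbe RNA-Seq Analysis with High-Frequency
    Conserved K-mers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of droplet single-microbe RNA sequencing (smRNA-seq)
    data without a reference genome. Reads carrying a 20 bp cell barcode and
    an 8 bp unique molecular identifier are whitelisted, extracted and
    quality-deduplicated; K-mers are counted across the cleaned reads; the
    knee of the K-mer rank curve separates high-frequency conserved K-mers
    (HCKs) from low-frequency noise; a sparse cell-by-HCK matrix replaces
    the usual cell-by-gene matrix for normalization, PCA, shared-nearest-
    neighbour clustering, cluster-quality metrics and marker K-mer
    detection. Per-cell taxonomic annotation aggregates read
    classifications over a taxonomy tree with a greedy root-to-leaf vote,
    and marker K-mers export to MEME one-hot motifs and six-frame-translated
    peptides with hypergeometric GO enrichment. A synthetic microbial
    community simulator provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
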