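Package: plastidkit
Title: Recovery, Structural Finishing and Validation of Chloroplast Genomes
    from Long Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recovering and finishing a chloroplast (plastid) genome
    from long, error-rich reads produced as a by-product of nuclear genome
    sequencing. Covers homology-based read extraction against a heterologous
    plastome reference with polymerase-read whitelisting, circularity
    detection, inverted-repeat discovery and quadripartite (LSC-IRa-SSC-IRb)
    partitioning, long-insert mate-pair validation with diagnosis of small
    single copy region misorientation, circular-aware coverage via dual
    linearization, majority-pileup consensus polishing, and whole-molecule
    assembly comparison with difference classification arbitrated by
    high-accuracy reads. A synthetic-data module generates plastomes, noisy
    long reads, fosmid-end pairs and nuclear background with ground truth so
    the whole workflow is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
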