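Package: straindelta
Title: Assembly-Level Variant, Methylome and Regulatory-Locus Analysis for Near-Identical Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two near-identical assembled bacterial genomes (a parent
    strain and an evolved daughter) by unique k-mer anchoring and gap alignment,
    normalizes and classifies the resulting variants against gene models
    (silent, conservative, nonconservative, nonsense, in-frame deletion),
    detects direct-repeat signatures flanking deletions, summarizes SMRT
    interpulse-duration (IPD) kinetics by cytosine context with Welch
    heteroscedastic t-tests, scans IUPAC degenerate methylation motifs and
    Spo0A-binding (0A box) sites, and computes intergenic gaps and pairwise
    percent identity. A seeded synthetic-data generator produces genomes,
    annotations, planted variant truth sets and simulated kinetics so the whole
    pipeline runs and is testable without any external download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
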