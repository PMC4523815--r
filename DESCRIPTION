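Package: tagbench
Title: Mock-Community Benchmarking of 16S rRNA Tag Sequencing Pipelines
Version: 0.1.0
Authors@R:
    person("Tagbench", "Developers", email = "tagbench@example.org", role = c("aut", "cre"))
Description: Tools to quantify primer and sequencing-platform bias in 16S
    rRNA amplicon (tag) surveys using defined mock communities. Computes
    expected community composition from DNA quantity, genome size and rRNA
    gene copy number (MED/MEND normalization); simulates amplicon reads
    with platform-specific error models (substitution-dominated MiSeq-like
    and homopolymer-indel 454-like modes), staggered primers and chimeras,
    with a per-read ground-truth table; implements read quality control
    (lenient/stringent filters, sliding-window trimming, paired-end
    merging, k-mer contaminant screening), alignment-based sequencing
    error profiling, OTU clustering with abundance and de novo chimera
    filters, bootstrap naive-Bayes taxonomic classification, and alpha and
    beta diversity (rarefaction, Bray-Curtis, UniFrac, PCoA) with
    Procrustes comparison of ordinations including a Monte Carlo
    significance test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
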