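Package: rerepkit
Title: Simulation and Analysis of Genome Re-Replication Sequencing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize DNA re-replication, the re-initiation of
    DNA synthesis on already-replicated chromatin when replication licensing
    control is lost. Provides a seeded stochastic simulator of origin
    licensing, firing, re-firing, fork stalling, BrdU strand substitution and
    CsCl density-gradient fractionation; replication-timing inference from
    binned S/G1 copy-number ratios with range-percentile and equal-count
    timing groups; condition-versus-condition replication origin usage
    analysis (normalization, log-ratio fraction stratification, peak size
    classes, dormant-origin detection); DNA-combing fiber statistics (fork
    rates, inter-origin distances, asymmetric-fork classification, rank-sum
    and chi-square tests); and chromatin association analyses (re-replication
    domain segmentation, peak-height quartiles, interval inclusion-ratio
    overlap statistics, eigen-score correlation, and origin-anchored signal
    profiles). A config-driven pipeline ties simulation to the analysis
    stages and writes bedGraph/BED/TSV outputs with a provenance manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
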