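Package: barseqfit
Title: Fitness Profiling of Pooled Barcoded Deletion Libraries by
    Barcode Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the fitness of pooled, molecularly
    barcoded deletion strains by deep sequencing (Bar-seq). Implements
    multiplexed read demultiplexing with exact index matching and
    mismatch-tolerant primer recognition, exact barcode counting against
    a strain catalog, counts-per-million normalization,
    growth-inhibition (GI) scoring across pool generations, robust
    median/NIQR hit cutoffs, G-test significance filtering,
    multi-experiment sensitive-hit calling, resistant-mutant ranking,
    quality-control statistics (replicate correlation, uptag/dntag
    agreement, spike-in linearity), hierarchical clustering of fitness
    profiles with the uncentered correlation metric, and a pooled-growth
    sequencing simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
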