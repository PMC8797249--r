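Package: ribomethr
Title: Quantitative Mapping of rRNA 2'-O-Methylation from Fragmentation
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of ribose 2'-O-methylation on
    ribosomal RNA from alkaline-fragmentation sequencing (RiboMethSeq-style)
    read-end counts. Computes per-position protection scores, aggregates
    replicated developmental-stage series into site-by-sample score matrices,
    calls methylated sites and classifies hypomethylation patterns across
    stages, clusters samples by methylation profile, predicts box C/D snoRNA
    guides for methylated positions via antisense-element search and the
    plus-five rule, and implements the low-dNTP primer-extension decision
    rule for orthogonal site confirmation. Ships a seeded synthetic-data
    generator (per-molecule alkaline cleavage with methylation-dependent
    bond protection, reverse-transcriptase stop profiles, and guide-bearing
    decoy transcriptomes) so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
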