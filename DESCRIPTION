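Package: fdrm
Title: Developmental Transcriptome Modification Analysis for Fungal RNA-Seq
Version: 0.1.0
Authors@R: person("fdrm", "maintainers", email = "fdrm@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of developmental transcriptome modification in
    multi-stage fungal RNA-seq designs: expression filtering, TMM normalization
    and relative-expression profiling with negative-binomial differential
    expression; classification and differential testing of alternative splicing
    events (eight event types, percent-spliced-in); RNA-editing site calling
    from paired DNA/RNA pileup evidence under replicate-aware filter rules;
    codon-level effect prediction for edits and isoforms with hypergeometric
    term enrichment; and phylotranscriptomic profiling (transcriptome age and
    divergence indices). Includes a synthetic-data generator with planted
    ground truth emulating a nine-stage, three-replicate developmental design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    edgeR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
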