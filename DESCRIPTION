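Package: toposeqr
Title: Strand-Specific Topo-Seq, ChIP-Seq and DRIP-Seq Track Analysis for Bacterial Topoisomerase I
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping topoisomerase I activity on bacterial genomes
    from strand-specific sequencing tracks. Implements 3'-end (N3E) track
    arithmetic with the two-stage induction/immunoprecipitation control
    subtraction chain, single-base topoisomerase cleavage-site (TCS) calling,
    cleavage/binding motif derivation from aligned TCS windows
    (position-frequency matrices, information content, cleavage-offset
    estimation), metagene and intergenic-region enrichment analyses with
    Welch/Bonferroni statistics, Monte-Carlo genomic interval overlap tests,
    and strand-specific DRIP-Seq R-loop signal processing with an RNase HI
    control. Ships a synthetic-data generator that emulates the signal
    structure of all assays so the full pipeline is testable on a desk-scale
    toy genome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
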