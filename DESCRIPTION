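Package: hicpair
Title: Comparative Analysis of Paired Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end comparison of chromatin architecture between two
    conditions (for example a tumor cell line versus its normal counterpart)
    from binned Hi-C contact matrices. Implements ICE matrix balancing,
    observed/expected transformation, segmented distance-decay exponents,
    A/B compartment calling with cross-condition switch classification,
    insulation-score TAD boundary detection and comparison, specific-loop
    comparison from BEDPE loop lists, inter-chromosomal translocation
    hotspot detection with WGS breakpoint double-confirmation and masking,
    structural-variant overlap enrichment, and contingency statistics
    joining compartment/TAD/loop alterations to differential gene
    expression. Ships a seeded synthetic-data generator producing paired
    contact maps with planted compartments, TADs, loops, biases and
    translocations plus a matched expression table, so every stage can be
    validated against machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
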