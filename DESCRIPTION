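Package: cassettexpress
Title: Gene Cassette Transcription Analysis for Large Integron Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for relative transcription of gene cassettes in
    large integron-associated arrays measured by degenerate-primer attC PCR and
    high-resolution fragment analysis. Predicts amplicon size classes from an
    annotated cassette array by in-silico PCR, calibrates and bins fragment
    peak tables, converts replicate cDNA/gDNA fingerprints into per-size-class
    relative expression ratios, calls conditional expression across stress
    treatment series, detects blocs of co-expressed adjacent cassettes, and
    localises intra-array promoters via sigma-70 motif scanning, nested-PCR
    interval logic and qPCR relative quantitation. Includes a synthetic-data
    generator that emulates a 116-cassette array with planted expression
    programs so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
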