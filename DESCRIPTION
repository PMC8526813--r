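Package: stromascope
Title: Stromal Microenvironment Analysis of Medulloblastoma Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signature-based stromal and immune scoring of bulk tumour
    transcriptomes, identification of receptor/ligand stroma-drivers and
    stroma-suppressors from differential expression combined with
    stromal-score correlation, thresholded co-expression networks ranked by
    closeness centrality, and per-cell stroma-activity and
    developmental-potential characterisation of single-cell data. Ships a
    synthetic-data generator with planted subgroup structure, stromal
    fractions and activity gradients so the full pipeline is testable
    without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
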