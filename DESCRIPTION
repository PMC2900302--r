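Package: tfcourse
Title: Time-Course Behavior Classification and Phase Enrichment of
    Transcription Factors in Osteoblast and Adipocyte Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for transcription-factor discovery from
    two-lineage differentiation time courses, modeled on genome-wide
    expression profiling of the mouse ST2 mesenchymal stromal line
    differentiating into osteoblasts and adipocytes. Selects
    transcription-factor genes by Gene Ontology annotation, classifies
    each gene's log2 expression ratio course relative to the uninduced
    control as up-, down-, up-and-down-regulated or unchanged using a
    fold-threshold-or-3SD rule, cross-tabulates behavior across
    lineages, assigns regulated genes to contiguous temporal phases of
    differentiation by peak timing, tests gene-family (e.g. bHLH,
    InterPro IPR001092) over-representation within each phase by a 2x2
    chi-square test, and ranks candidate lineage-switch genes
    up-regulated in one lineage and down-regulated in the other. A
    seeded synthetic-data module generates phase-structured datasets,
    including a deterministic reference fixture, so the whole pipeline
    is testable without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
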