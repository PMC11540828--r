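Package: fibromod
Title: Phase-Specific Gene Co-Expression Modules as Biomarkers of
    Chemically Induced Lung Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives phase-specific co-expression biomarker modules for
    chemically induced lung fibrosis from treated-versus-control time-course
    transcriptomics, and applies them to external concentration-response
    data.  Implements weighted gene co-expression network construction
    (soft-threshold adjacency, topological overlap, average-linkage
    clustering, tree cutting, eigengene/hub-gene summaries, module merging),
    a phase-wise differential-activity statistic for module selection,
    gene-set and biomarker annotation, and projection of frozen modules
    onto targeted-panel differential-expression tables (DEG-fraction
    activation calls, module scores, concentration-trend tests).  A
    synthetic-data generator with planted module structure emulates the
    in vivo bleomycin-style time course and an in vitro concentration
    series so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
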