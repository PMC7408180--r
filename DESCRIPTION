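Package: EventSieve
Title: Database-Backed Filtering of Machine-Reading-Extracted Biomolecular Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scores and selects biomolecular interactions extracted from the
    literature by machine-reading engines (protein-protein, protein-chemical and
    protein-biological-process events) by matching them against a locally built,
    unified interaction knowledge base assembled from STRING, STITCH, GO
    annotation, BioGRID and Reactome dump files. Provides subscore threshold
    policies (experimental, curated-database and text-mining confidence scores),
    literature-based novelty and between-paper duplicate flags, citation-based
    expansion of reading sets, retrieval of candidate papers from database
    citations, and a precision/recall evaluation harness with single-score and
    combination threshold sweeps. Includes a seeded generator of miniature dump
    files in the public dialects so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'id_mapping.R'
    'kb_store.R'
    'kb_io.R'
    'interactions_io.R'
    'literature_flags.R'
    'filter_engine.R'
    'kb_expansion.R'
    'evaluation.R'
    'synth_fixtures.R'
    'cli.R'
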