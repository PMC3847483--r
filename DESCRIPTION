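Package: orthopath
Title: Multi-Template Reciprocal-Best-Hit Metabolic Pathway Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs species-specific metabolic pathways by comparative
    genomics against multiple well-annotated template proteomes. Implements
    filtered reciprocal-best-hit ortholog annotation, match-score (MS) and
    conservation-score (CS) confidence scoring with A/B/C region
    classification, EC-number based pathway assembly with metabolic gap
    detection, validation against known gene sets, and overlay of
    probe-level transcriptome data onto the reconstructed pathway graph.
    Includes a Smith-Waterman local alignment engine with Karlin-Altschul
    E-values, readers for FASTA, tabular BLAST and pathway templates,
    GraphML/JSON graph export, and a seeded synthetic-data generator with a
    ground-truth manifest for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    xml2,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
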