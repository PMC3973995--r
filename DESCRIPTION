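Package: aderex
Title: Knowledge-Based Extraction of Adverse Drug Event Relations from Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A knowledge-based pipeline for extracting drug-adverse effect
    relations from biomedical abstracts. Drugs and disorders are recognized
    by dictionary look-up with term normalization, refined by five rule-based
    post-processing modules (coordination resolution, abbreviation expansion,
    term variation, boundary correction, concept filtering) driven by a
    bundled part-of-speech tagger and noun-phrase chunker. A relation is
    asserted for a drug-disorder pair when the shortest-path distance between
    their concepts in a typed concept graph falls below a threshold, refined
    by a trainable relation-type filter that discards paths carrying relation
    types over-represented among false positives. Includes boundary-exact
    precision/recall/F evaluation, stage-wise reporting, an error taxonomy,
    and seeded generators for a toy lexicon, a concept graph with planted
    structure, and an annotated corpus, so the full pipeline is testable
    without licensed vocabularies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
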