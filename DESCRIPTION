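Package: topicminer
Title: Topic-Specific Molecular Interaction Catalogues from Literature-Mined Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a topic-specific catalogue of molecular
    interactions from biomedical literature with text-mining assistance.
    Provides a weighted term dictionary with case-sensitive longest-match
    retrieval, document relevance scoring by term specificity and section
    position, grouping of pre-extracted nested molecular events (GENIA-style
    event chains) into unique interactions keyed on canonical signatures,
    contextual annotation (point mutations linked to proteins via
    priority-ranked textual patterns, Gene Ontology terms, negation and
    speculation polarity, anatomy), term-to-event relevancy scoring on a
    5-100 scale, and the curation and enrichment statistics used to validate
    such a catalogue (confusion metrics, Cohen's kappa, Fisher enrichment,
    precision stratification, and a logistic triage model on extractor
    confidence). A deterministic synthetic-corpus generator produces fully
    annotated fixtures with a ground-truth manifest so every stage can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
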