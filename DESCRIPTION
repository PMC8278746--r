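Package: famhx
Title: Family History Information Extraction from Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting family history information from clinical
    narrative: token-level recognition of ten clinical and modifier entity
    types (family members, the patient, the index patient, conditions,
    events, side-of-family, age, negation, amount and temporal expressions)
    and classification of five binary relation types (Holder, Modifier,
    Related_to, Subset, Partner) between them. Includes readers and writers
    for brat standoff annotation and CoNLL-U layers, sparse indicator
    feature templates over lexical, part-of-speech and dependency context,
    a dictionary baseline and a linear-classifier tagger with greedy
    left-to-right decoding, exhaustive within-sentence relation-candidate
    generation, weighted precision/recall/F1 evaluation with k-fold
    cross-validation and inter-annotator agreement, and a pedigree-driven
    synthetic corpus generator for download-free development and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
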