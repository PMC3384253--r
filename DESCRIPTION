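Package: bioevents
Title: Biomedical Event Extraction with Search-Based Structured Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts typed, possibly nested biomolecular events (gene
    expression, phosphorylation, binding, regulation and related types)
    from sentence-level text annotated in the BioNLP standoff format.
    Event extraction is decomposed into trigger recognition, Theme
    assignment and Cause assignment, followed by rule-based event
    construction.  The stage classifiers can be trained independently or
    jointly with the SEARN search-based structured prediction algorithm,
    using a multiclass cost-sensitive passive-aggressive learner, focused
    costing, weighted false-positive/false-negative loss for
    precision-recall control, and feature-augmentation domain adaptation
    across abstracts and full papers.  Includes readers and writers for
    standoff (.a1/.a2) and dependency-parse files, an event-level
    evaluator, and a synthetic corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
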