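Package: linkeval
Title: Evaluation and Error Analysis for Clinical Entity Linking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and error-analysis toolkit for span-based clinical
    entity linking against a hierarchical terminology such as SNOMED CT.
    Implements the per-concept character-level intersection-over-union
    (IoU) metric with mean and class-weighted aggregates and bootstrap
    confidence intervals, an inter-annotator agreement measure, a
    five-way error taxonomy over span and link mistakes, concept-level
    difficulty features (span-string entropy, annotation-ambiguity
    entropy, hierarchy depth, training frequency), a character-level
    majority-vote ensemble combiner, and a seeded synthetic benchmark
    generator (terminology, sectioned documents, gold annotations, and
    parameterised prediction noise) so the whole pipeline can be
    exercised without access to restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
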