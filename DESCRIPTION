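Package: spanagree
Title: Inter-Rater Agreement for Span-Level Clinical Concept Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring inter-rater agreement on span-level
    annotation of signs and symptoms in clinical notes. Builds agreement
    units from pairs of annotators (one unit per span in the union of the
    two raters' annotations, plus one agreeing unit per screen that neither
    rater annotated), computes concordance (unadjusted agreement) and
    Cohen's Kappa for the text-span and category-label tasks, assigns the
    seven-way category-label taxonomy (unigram through extended, compound,
    tabular), normalizes text spans to ontology concepts through a phrase
    lookup table with a character-trigram similarity fallback, and supplies
    a synthetic clinical-note generator with configurable simulated
    annotators (sensitivity, false positives, boundary jitter, label
    confusion, negation errors) so the whole pipeline is testable without
    protected health data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
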