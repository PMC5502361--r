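Package: litriage
Title: Ranking-Based Literature Triage for Interaction and Modification Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks MEDLINE abstracts for biocuration triage along two
    annotation axes: protein-protein interactions (PPI) and
    post-translational modifications (PTM). Combines an Okapi BM25
    vector-space retrieval score with axis-specific concept-density
    statistics obtained by stem-based dictionary annotation, supports
    query refinement with axis trigger keywords, provides a Boolean
    recency-ranked baseline, and evaluates ranked runs against TREC-style
    relevance judgements (P@1, MRR, MAP). Includes a synthetic corpus
    generator so the full triage pipeline can be benchmarked end to end
    without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
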