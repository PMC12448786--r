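Package: literag
Title: Retrieval-Augmented Question Answering over Literature Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline engine for evidence-grounded question answering over a
    local corpus of research documents. Implements integrated multi-strategy
    retrieval (question-, keyword- and virtual-answer-based queries at abstract
    and full-text level) fused by a weighted normalized aggregator, followed by
    progressive answer generation with sequential relevance checking,
    self-reflective support scoring and a final deep-reasoning pass. Also
    provides a dual-layer (entity-level and document-level) knowledge-graph
    construction workflow with two-stage entity normalization and provenance-
    carrying edges, an evaluation harness for document-retrieval
    precision/recall/F1 and judge-based answer scoring with ablation runners,
    and a synthetic-corpus generator so the full pipeline is testable with
    deterministic mock embedding and language-model backends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
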