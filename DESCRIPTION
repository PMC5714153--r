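Package: datamedrank
Title: Term-Relevance Ranking and Evaluation for Biomedical Dataset Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A retrieval engine for biomedical dataset records in the
    DataMed/bioCADDIE dump format. Provides corpus, qrels, run and
    word-embedding readers and writers; query and corpus normalization with
    Porter stemming; query expansion by k-nearest neighbours in a word
    embedding space under two weighting models; the robust term relevance
    logic (RTRL) similarity measure that ranks documents into integer
    relevance bins by query-term relevance class with within-bin tf-idf
    tie-breaking; an InL2 divergence-from-randomness baseline scorer;
    category-constrained result boosting against the UniProt topic scheme;
    linear rank fusion; and an evaluation stack with inferred average
    precision, inferred NDCG, precision at 10 with and without partial
    relevance, NDCG at 10, and the unanimous improvement ratio, all with
    configurable handling of pooled-but-unjudged documents. A seeded
    synthetic-collection generator makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
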