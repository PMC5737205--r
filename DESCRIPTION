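Package: biodatasearch
Title: Fielded Search and Query Expansion for Biomedical Dataset Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for indexing and retrieving biomedical dataset metadata
    records aggregated from heterogeneous repositories. Provides a per-field
    inverted index with TF-IDF vector-space scoring, an entity-aware
    multi-field query builder with clause and concept boosting and a
    data-category filter, query expansion by Rocchio relevance feedback
    (pseudo-relevance or judgment-based) and by an idf-ranked biomedical
    lexicon, TREC-format run and qrels input/output, standard and inferred
    retrieval metrics (P@k, Recall, AP/MAP, NDCG, infAP, infNDCG), and a
    seeded synthetic-collection generator with planted graded relevance for
    end-to-end experimentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
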