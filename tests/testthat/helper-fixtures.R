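# Shared micro-fixtures, built in code.

three_doc_records <- function() {
  list(
    dataset_record("d1", "repoA", "Protein structure",
                   list(title = "chemotaxis protein")),
    dataset_record("d2", "repoA", "Unspecified",
                   list(title = "protein structure")),
    dataset_record("d3", "repoB", "Gene expression",
                   list(title = "gene expression"))
  )
}

tiny_lexicon <- function() {
  biomed_lexicon(
    entry_id = c("G1", "G2", "O1", "D1"),
    entity_type = c("gene", "gene", "organism", "disease"),
    canonical_name = c("TP53", "CheY", "Homo sapiens", "neoplasm"),
    synonyms = list(c("p53", "tumor protein p53"), c("chey protein"),
                    c("human"), c("tumor", "cancer")))
}

# A random micro-corpus of raw token lists over a small vocabulary; used by
# the brute-force scorer comparisons. Returns records plus the raw token
# lists keyed by doc and field (the analyzer is bypassed on purpose: terms
# are already stems).
random_micro_corpus <- function(n_docs, fields = c("title", "description"),
                                vocab = paste0("t", 1:12)) {
  records <- vector("list", n_docs)
  tokens <- vector("list", n_docs)
  ids <- sprintf("m%02d", seq_len(n_docs))
  for (i in seq_len(n_docs)) {
    fl <- list()
    tk <- list()
    for (f in fields) {
      if (stats::runif(1) < 0.15) next  # some docs lack some fields
      n_tok <- sample(1:8, 1)
      toks <- sample(vocab, n_tok, replace = TRUE)
      fl[[f]] <- paste(toks, collapse = " ")
      tk[[f]] <- toks
    }
    records[[i]] <- dataset_record(ids[i], "r", "Unspecified", fl)
    tokens[[i]] <- tk
  }
  names(tokens) <- ids
  list(records = records, tokens = tokens, ids = ids, vocab = vocab,
       fields = fields)
}

random_query_for <- function(corpus, max_clauses = 3) {
  n_cl <- sample(seq_len(max_clauses), 1)
  clauses <- lapply(seq_len(n_cl), function(i) {
    query_clause(sample(corpus$fields, 1),
                 sample(corpus$vocab, sample(1:4, 1)),
                 boost = sample(c(1, 1, 2, 0.5), 1),
                 term_boosts = sample(c(1, 2), 1))
  })
  multifield_query(clauses)
}

# random ranking + graded judgments for metric comparisons
random_eval_instance <- function(max_docs = 50) {
  n <- sample(3:max_docs, 1)
  ids <- sprintf("e%03d", seq_len(n))
  ranked <- sample(ids, sample(seq_len(n), 1))
  judged <- sample(ids, sample(seq_len(n), 1))
  grades <- stats::setNames(sample(c(-1L, 0L, 1L, 2L), length(judged),
                                   replace = TRUE), judged)
  list(ranked = ranked, grades = grades)
}

small_generator_config <- function(seed = 1) {
  generator_config(
    seed = seed,
    repositories = list(
      list(name = "alpha", category = "Gene expression", n_docs = 60,
           fields = c("title", "description", "keywords", "organisms")),
      list(name = "beta", category = "Protein structure", n_docs = 60,
           fields = c("title", "description", "organisms", "genes"),
           pmids = TRUE),
      list(name = "gamma", category = "Unspecified", n_docs = 80,
           fields = c("title", "description", "keywords", "organisms"))),
    n_background = 200, n_theme = 60,
    n_genes = 20, n_organisms = 20, n_diseases = 5,
    n_queries = 4, n_rel2 = 5, n_rel1 = 3, n_nonrel = 10,
    n_distractors = 8, n_topic_terms = 3, n_theme_terms = 4,
    frac_category_queries = 0.5)
}
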