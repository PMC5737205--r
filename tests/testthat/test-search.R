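test_that("the worked single-clause score is reproduced exactly", {
  idx <- build_index(three_doc_records())
  q <- multifield_query(query_clause("title", "protein"))
  # coord 1/1 * sqrt(1) * idf(protein)^2 * boost 1 * 1/sqrt(2)
  expect_equal(score_document(q, "d1", idx), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(score_document(q, "d3", idx), 0)
  expect_error(score_document(q, "missing", idx), "unknown doc_id")
})

test_that("boost scales a clause contribution linearly", {
  idx <- build_index(three_doc_records())
  s1 <- score_document(multifield_query(query_clause("title", "protein")),
                       "d1", idx)
  s2 <- score_document(multifield_query(query_clause("title", "protein",
                                                     boost = 2)),
                       "d1", idx)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # per-term boost behaves the same way
  s3 <- score_document(multifield_query(query_clause("title", "protein",
                                                     term_boosts = 2)),
                       "d1", idx)
  expect_equal(s3, 2 * s1, tolerance = 1e-12)
})

test_that("ranking orders by score with doc_id tie-break and truncates", {
  idx <- build_index(three_doc_records())
  q <- multifield_query(query_clause("title", "protein"))
  r <- search_index(q, idx)
  expect_identical(r$doc_id, c("d1", "d2"))   # tied scores, id order
  expect_true(all(diff(r$score) <= 0))
  expect_identical(search_index(q, idx, top_n = 1)$doc_id, "d1")
  expect_identical(nrow(search_index(q, build_index(list()))), 0L)
})

test_that("the category filter restricts candidates but never Unspecified", {
  idx <- build_index(three_doc_records())
  q <- multifield_query(list(query_clause("title", c("protein", "gene",
                                                     "express", "structur"))),
                        category_filter = "Gene expression")
  r <- search_index(q, idx)
  # d1 is Protein structure -> filtered; d2 Unspecified and d3 match
  expect_setequal(r$doc_id, c("d2", "d3"))
  # property over generated collections: no Unspecified document that
  # scores is ever excluded by a filter
  coll <- generate_collection(small_generator_config(seed = 7))
  idx2 <- build_index(coll$records)
  cats <- stats::setNames(vapply(coll$records, `[[`, character(1), "category"),
                          vapply(coll$records, `[[`, character(1), "doc_id"))
  for (i in 1:3) {
    qq <- multifield_query(query_clause("title", c("w0051", sprintf("w%04d", 30 + i))),
                           category_filter = "Protein structure")
    no_filter <- search_index(multifield_query(qq$clauses), idx2, top_n = 500)
    with_filter <- search_index(qq, idx2, top_n = 500)
    unspec <- no_filter$doc_id[cats[no_filter$doc_id] == "Unspecified"]
    expect_true(all(unspec %in% with_filter$doc_id))
    kept_cats <- unique(cats[with_filter$doc_id])
    expect_true(all(kept_cats %in% c("Protein structure", "Unspecified")))
  }
})

test_that("adding a clause never shrinks the candidate set", {
  coll <- generate_collection(small_generator_config(seed = 9))
  idx <- build_index(coll$records)
  set.seed(11)
  for (i in 1:5) {
    terms1 <- sample(c("w0040", "w0051", "w0062", "theme010"), 2)
    q1 <- multifield_query(query_clause("title", terms1))
    q2 <- multifield_query(list(query_clause("title", terms1),
                                query_clause("description", c("w0033", "theme002"))))
    r1 <- search_index(q1, idx, top_n = 10000)
    r2 <- search_index(q2, idx, top_n = 10000)
    expect_true(all(r1$doc_id %in% r2$doc_id))
  }
})

test_that("scores match a brute-force implementation of the formula", {
  set.seed(402)
  for (trial in 1:40) {
    corpus <- random_micro_corpus(sample(2:20, 1))
    idx <- build_index(corpus$records,
                       analyzer_config(stopwords = character(0),
                                       stemmer = "none"))
    q <- random_query_for(corpus)
    for (doc_id in sample(corpus$ids, min(4, length(corpus$ids)))) {
      expect_equal(score_document(q, doc_id, idx),
                   oracle_score(q, corpus$tokens, corpus$tokens, doc_id),
                   tolerance = 1e-9)
    }
    # single one-term clause: ranking order equals sqrt(tf)/sqrt(len) order
    term <- sample(corpus$vocab, 1)
    q1 <- multifield_query(query_clause("title", term))
    r <- search_index(q1, idx, top_n = 100)
    if (nrow(r) > 1) {
      key <- vapply(r$doc_id, function(d) {
        toks <- corpus$tokens[[d]][["title"]]
        sqrt(sum(toks == term)) / sqrt(length(toks))
      }, numeric(1))
      expect_true(all(diff(key) <= 1e-12))
    }
  }
})

test_that("TREC run files round-trip with deterministic re-sorting", {
  r <- run_ranking("q1", c("a", "b", "c"), c(3, 2, 2), tag = "t")
  path <- withr::local_tempfile()
  write_run(r, path)
  back <- read_run(path)
  expect_identical(back$doc_id, c("a", "b", "c"))
  expect_identical(back$rank, 1:3)
  # shuffled lines re-sort to the same ranking
  writeLines(rev(readLines(path)), path)
  expect_identical(read_run(path)$doc_id, c("a", "b", "c"))
  expect_error(read_run(withr::local_tempfile(lines = "q1 Q0 d1 1")),
               "expected 6")
})
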