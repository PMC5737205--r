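test_that("the Rocchio combination reproduces the worked example exactly", {
  fb <- feedback_sets(relevant = list(r1 = c(b = 2)),
                      irrelevant = list(n1 = c(a = 1, b = 1)))
  qp <- rocchio_vector(c(a = 1), fb)
  expect_equal(qp[["a"]], 0.9, tolerance = 1e-15)
  expect_equal(qp[["b"]], 0.9, tolerance = 1e-15)
})

test_that("degenerate Rocchio parameter settings behave as contracted", {
  fb <- feedback_sets(relevant = list(r1 = c(b = 2)),
                      irrelevant = list(n1 = c(a = 1, b = 1)))
  # beta = gamma = 0 returns alpha * Q on the union vocabulary
  qp <- rocchio_vector(c(a = 2), fb, rocchio_params(alpha = 1.5, beta = 0,
                                                    gamma = 0))
  expect_equal(qp[["a"]], 3)
  expect_equal(qp[["b"]], 0)
  # empty irrelevant set: no subtraction term
  qp2 <- rocchio_vector(c(a = 1), feedback_sets(relevant = list(r1 = c(b = 2))))
  expect_equal(qp2[["a"]], 1)
  expect_equal(qp2[["b"]], 1)
  # negative coordinates clamp to zero
  qp3 <- rocchio_vector(c(), feedback_sets(irrelevant = list(n1 = c(x = 5))),
                        rocchio_params())
  expect_equal(qp3[["x"]], 0)
  expect_error(feedback_sets(relevant = list(d = c(a = 1)),
                             irrelevant = list(d = c(a = 1))), "disjoint")
})

test_that("Rocchio matches brute-force dense arithmetic on random instances", {
  set.seed(77)
  for (trial in 1:60) {
    universe <- paste0("u", seq_len(sample(3:30, 1)))
    rand_vec <- function() {
      terms <- sample(universe, sample(seq_along(universe), 1))
      stats::setNames(round(stats::runif(length(terms), 0, 5), 3), terms)
    }
    nr <- sample(0:10, 1); nn <- sample(0:10, 1)
    rel <- if (nr) lapply(seq_len(nr), function(i) rand_vec()) else list()
    irr <- if (nn) lapply(seq_len(nn), function(i) rand_vec()) else list()
    names(rel) <- if (nr) paste0("r", seq_len(nr))
    names(irr) <- if (nn) paste0("n", seq_len(nn))
    qv <- rand_vec()
    a <- stats::runif(1, 0, 2); b <- stats::runif(1, 0, 1)
    g <- stats::runif(1, 0, 0.5)
    got <- rocchio_vector(qv, feedback_sets(rel, irr),
                          rocchio_params(alpha = a, beta = b, gamma = g))
    want <- oracle_rocchio(qv, rel, irr, a, b, g, universe)
    expect_equal(got[universe][want > 0], want[want > 0], tolerance = 1e-12)
    expect_true(all(got >= 0))
  }
})

test_that("expansion term selection excludes originals and breaks ties lexicographically", {
  qp <- c(a = 0.9, b = 0.9, c = 0.4)
  ex <- select_expansion_terms(qp, original_terms = "a", n_terms = 1)
  expect_identical(ex$terms, "b")
  expect_equal(ex$weights, 0.9)
  # equal weights: lexicographically smaller term first
  ex2 <- select_expansion_terms(c(zed = 0.5, ant = 0.5, mid = 0.7),
                                character(0), 3)
  expect_identical(ex2$terms, c("mid", "ant", "zed"))
  expect_identical(select_expansion_terms(qp, "a", 0)$terms, character(0))
  # zero and negative weights never selected
  ex3 <- select_expansion_terms(c(x = 0, y = 1e-9), character(0), 5)
  expect_identical(ex3$terms, "y")
})

test_that("PRF feedback takes source-field vectors of the top-k initial results", {
  coll <- generate_collection(small_generator_config(seed = 4))
  idx <- build_index(coll$records)
  q <- baseline_query(coll$queries$text[1])
  params <- rocchio_params(prf_k = 5)
  fb <- prf_feedback(idx, q, params)
  initial <- search_index(q, idx, top_n = 5)
  expect_identical(names(fb$relevant), initial$doc_id)
  expect_length(fb$irrelevant, 0)
  expect_identical(fb$relevant[[1]],
                   doc_vector(initial$doc_id[1], "description", idx))
  # deterministic
  fb2 <- prf_feedback(idx, q, params)
  expect_identical(fb, fb2)
  # source_field switches the vector source
  fb3 <- prf_feedback(idx, q, rocchio_params(prf_k = 5, source_field = "title"))
  expect_identical(fb3$relevant[[1]],
                   doc_vector(initial$doc_id[1], "title", idx))
  # fewer hits than k
  narrow <- multifield_query(query_clause("genes", "gen001x"))
  fbn <- prf_feedback(idx, narrow, rocchio_params(prf_k = 10))
  expect_true(length(fbn$relevant) <= 10)
})

test_that("judgment-based feedback splits by grade and excludes unjudged", {
  recs <- lapply(1:4, function(i) {
    dataset_record(paste0("d", i), "r",
                   fields = list(description = paste("alpha beta", i)))
  })
  idx <- build_index(recs)
  qr <- qrels(rep("q1", 4), c("d1", "d2", "d3", "d4"), c(2, 1, 0, -1))
  fb <- oracle_feedback(qr, "q1", idx)
  expect_setequal(names(fb$relevant), c("d1", "d2"))
  expect_identical(names(fb$irrelevant), "d3")
  expect_error(oracle_feedback(qr, "q99", idx), "not present")
})

test_that("lexicon expansion ranks synonym terms by idf and excludes originals", {
  lex <- tiny_lexicon()
  recs <- list(
    dataset_record("d1", "r", fields = list(description = "p53 pathway")),
    dataset_record("d2", "r", fields = list(description = "p53 p53 signaling")),
    dataset_record("d3", "r", fields = list(description = "tumor biology")),
    dataset_record("d4", "r", fields = list(description = "tumor tumor tumor")),
    dataset_record("d5", "r", fields = list(description = "unrelated text")))
  idx <- build_index(recs)
  tq <- tag_entities("studies of TP53", lex)
  ex <- lexicon_expand(tq, lex, idx, n_terms = 2)
  # candidates: p53 (df 2), tumor (df 2), protein (df 0) from G1 synonyms
  # "protein" is rarest so it ranks first
  expect_identical(ex$terms[1], "protein")
  expect_identical(ex$method, "lexicon")
  expect_false("tp53" %in% ex$terms)
  # no mentions -> empty expansion
  ex2 <- lexicon_expand(tag_entities("nothing here", lex), lex, idx)
  expect_length(ex2$terms, 0)
})

test_that("applying an expansion appends to always-on clauses idempotently", {
  lex <- tiny_lexicon()
  tq <- tag_entities("find gene expression of TP53 in Homo sapiens", lex,
                     rules = default_category_rules())
  q <- build_query(tq)
  ex <- structure(list(original_terms = tq$analyzed_terms,
                       terms = c("extra1", "extra2"), weights = c(2, 1),
                       method = "rocchio_prf"),
                  class = "expanded_query")
  q2 <- apply_expansion(q, ex)
  for (cl in q2$clauses) {
    if (cl$field %in% c("title", "description", "article_title")) {
      expect_true(all(c("extra1", "extra2") %in% cl$terms))
      expect_true(all(cl$term_boosts[cl$terms %in% ex$terms] == 1))
    } else {
      expect_false(any(ex$terms %in% cl$terms))
    }
  }
  expect_identical(apply_expansion(q2, ex), q2)   # no duplicates
  empty <- structure(list(original_terms = character(0), terms = character(0),
                          weights = numeric(0), method = "rocchio_prf"),
                     class = "expanded_query")
  expect_identical(apply_expansion(q, empty), q)
})

test_that("oracle expansion terms occur in relevant source fields on separable data", {
  coll <- generate_collection(small_generator_config(seed = 8))
  idx <- build_index(coll$records)
  for (qid in coll$queries$query_id) {
    tagged <- tag_entities(coll$queries$text[coll$queries$query_id == qid],
                           coll$lexicon, rules = default_category_rules())
    q <- build_query(tagged)
    ex <- rocchio_expand(q, idx, rocchio_params(), qrels = coll$qrels,
                         query_id = qid)
    rel_docs <- coll$qrels$doc_id[coll$qrels$query_id == qid &
                                    coll$qrels$grade >= 1]
    for (tm in ex$terms) {
      in_rel <- any(vapply(rel_docs, function(d) {
        tm %in% names(doc_vector(d, "description", idx))
      }, logical(1)))
      expect_true(in_rel, info = paste(qid, tm))
    }
  }
})
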