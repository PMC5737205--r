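test_that("qrels parsing enforces the four-value grade scale", {
  path <- withr::local_tempfile(lines = c("q1 0 d1 2", "q1 0 d2 -1",
                                          "q2 0 d1 0"))
  qr <- read_qrels(path)
  expect_identical(qr$grade, c(2L, -1L, 0L))
  bad <- withr::local_tempfile(lines = c("q1 0 d1 2", "q1 0 d2 3"))
  expect_error(read_qrels(bad), "line 2")
  short <- withr::local_tempfile(lines = "q1 d1 2")
  expect_error(read_qrels(short), "line 1")
  expect_error(qrels("q1", c("d1", "d1"), c(1, 2)), "duplicate")
  roundtrip <- withr::local_tempfile()
  write_qrels(qr, roundtrip)
  expect_identical(read_qrels(roundtrip), qr)
})

test_that("precision, recall and AP worked examples", {
  grades <- c(r1 = 2L, r2 = 1L, x = 0L, u = -1L)
  # relevant at ranks 1 and 3 of a length-4 ranking
  ranked <- c("r1", "x", "r2", "u")
  expect_equal(precision_at_k(ranked, grades, 10), 0.2)
  expect_equal(precision_at_k(ranked, grades, 2), 0.5)
  expect_equal(precision_at_k(c("r1", "r2"), grades, 2), 1.0)
  # padding: short rankings divide by k, not by length
  expect_equal(precision_at_k(c("r1", "x", "r2", "x2"), grades, 10), 0.2)
  expect_equal(recall_at_cutoff(ranked, grades), 1.0)
  expect_equal(recall_at_cutoff(ranked, grades, cutoff = 1), 0.5)
  expect_equal(recall_at_cutoff(ranked, grades, cutoff = 0), 0)
  # AP of [R, N, R] with 2 relevant total
  expect_equal(average_precision(c("r1", "x", "r2"), grades),
               (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(average_precision(c("r1", "r2", "x"), grades), 1.0)
  expect_equal(average_precision(c("x", "u"), grades), 0.0)
  expect_warning(average_precision("x", c(x = 0L)), "no relevant")
})

test_that("NDCG worked example and monotonicity under a better swap", {
  grades <- c(a = 2L, b = 0L, c = 1L)
  got <- ndcg_at_k(c("a", "b", "c"), grades)
  expect_equal(got, 3.5 / (3 + 1 / log2(3)), tolerance = 1e-12)
  expect_equal(ndcg_at_k(c("a", "c", "b"), grades), 1.0)
  # moving the higher-graded document up never decreases NDCG
  expect_true(ndcg_at_k(c("c", "a", "b"), grades) <= got + 1e-12)
  expect_warning(ndcg_at_k("b", c(b = 0L)), "undefined")
})

test_that("standard metrics agree with the naive reference evaluator", {
  set.seed(2024)
  for (trial in 1:1000) {
    inst <- random_eval_instance()
    g <- inst$grades
    r <- inst$ranked
    if (any(g >= 1)) {
      expect_equal(average_precision(r, g), oracle_ap(r, g),
                   tolerance = 1e-6)
      expect_equal(recall_at_cutoff(r, g, 10), oracle_recall(r, g, 10),
                   tolerance = 1e-6)
    }
    for (k in c(5, 10)) {
      expect_equal(precision_at_k(r, g, k), oracle_p_at_k(r, g, k),
                   tolerance = 1e-6)
    }
    if (any(g >= 1)) {
      expect_equal(ndcg_at_k(r, g, 10), oracle_ndcg(r, g, 10),
                   tolerance = 1e-6)
    }
  }
})

test_that("inferred metrics reduce exactly to their counterparts at full sampling", {
  set.seed(55)
  for (trial in 1:50) {
    inst <- random_eval_instance()
    g <- inst$grades[inst$grades >= 0]    # sampled pool excludes unjudged
    if (!any(g >= 1)) next
    expect_equal(inferred_ap(inst$ranked, g, rate = 1),
                 average_precision(inst$ranked, inst$grades), tolerance = 1e-12)
    expect_equal(inferred_ndcg(inst$ranked, g, rate = 1),
                 ndcg_at_k(inst$ranked, inst$grades), tolerance = 1e-12)
  }
  # a single judged, relevant document at rank 1
  expect_equal(inferred_ap("d1", c(d1 = 2L), rate = 0.25), 1.0)
  expect_error(inferred_ap("d1", stats::setNames(integer(0), character(0)),
                           rate = 0.5), "no sampled")
  expect_error(inferred_ndcg("d1", stats::setNames(integer(0), character(0)),
                             rate = 0.5), "no sampled")
})

test_that("overlap similarity implements the min-normalized formula", {
  expect_equal(overlap_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_similarity(c("a"), c("b", "c")), 0)
  expect_equal(overlap_similarity(c("a", "b", "c"), c("b", "c", "d", "e")),
               2 / 3, tolerance = 1e-12)
  expect_error(overlap_similarity(character(0), "a"), "empty")
  # brute-force enumeration over all non-empty subsets of a 6-term universe
  universe <- letters[1:6]
  subsets <- lapply(seq_len(2^6 - 1), function(m) {
    universe[bitwAnd(m, 2^(0:5)) > 0]
  })
  set.seed(1)
  for (pair in sample(length(subsets)^2, 400)) {
    i <- (pair - 1) %/% length(subsets) + 1
    j <- (pair - 1) %% length(subsets) + 1
    expect_equal(overlap_similarity(subsets[[i]], subsets[[j]]),
                 oracle_overlap(subsets[[i]], subsets[[j]]),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_run aggregates per query and skips unjudged queries", {
  run <- rbind(run_ranking("q1", c("d1", "d2"), c(2, 1)),
               run_ranking("q9", "d1", 1))
  class(run) <- c("run_ranking", "data.frame")
  qr <- qrels(c("q1", "q1"), c("d1", "d2"), c(2, 0))
  expect_warning(rep <- evaluate_run(run, qr), "absent from qrels")
  expect_identical(rep$per_query$query_id, "q1")
  expect_equal(rep$per_query$ap, 1)
  expect_equal(unname(rep$means["p10"]), 0.1)
})

test_that("overlap analysis separates planted relevant from irrelevant documents", {
  coll <- generate_collection(small_generator_config(seed = 6))
  rel <- overlap_by_field(coll$records, coll$queries, coll$qrels, grades = 2)
  non <- overlap_by_field(coll$records, coll$queries, coll$qrels, grades = 0)
  rel_d <- rel$overlap[rel$field == "description"]
  non_d <- non$overlap[non$field == "description"]
  expect_true(mean(rel_d) > mean(non_d))
  st <- overlap_stats(rel)
  expect_true(all(c("field", "median", "q1", "q3") %in% names(st)))
  expect_true(all(st$median >= st$q1 & st$median <= st$q3))
})
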