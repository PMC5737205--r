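#' Query expansion: Rocchio relevance feedback and lexicon lookup
#'
#' Expansion enriches a query with terms likely to occur in relevant
#' documents. Two term sources are implemented: the Rocchio combination of
#' the query vector with centroids of relevant and irrelevant document
#' vectors,
#'
#'   Q' = alpha * Q + (beta / |DR|) * sum(dr) - (gamma / |DNR|) * sum(dnr)
#'
#' fed either by pseudo-relevance feedback (the top-k documents of an
#' initial run, positive feedback only) or by graded judgments (relevant
#' and irrelevant sets both); and a biomedical-lexicon method that ranks
#' the synonyms of entities mentioned in the query by collection idf.
#'
#' @name expansion
NULL

#' Rocchio parameters
#'
#' @param alpha Weight of the original query vector, default 1.
#' @param beta Weight of the relevant-centroid term, default 0.5.
#' @param gamma Weight of the irrelevant-centroid term, default 0.1.
#' @param prf_k Feedback depth for pseudo-relevance feedback, default 10.
#' @param n_terms Number of expansion terms kept, default 5.
#' @param source_field Field whose document vectors feed the combination,
#'   default `"description"`.
#' @return An object of class `rocchio_params`.
#' @export
rocchio_params <- function(alpha = 1, beta = 0.5, gamma = 0.1,
                           prf_k = 10, n_terms = 5,
                           source_field = "description") {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, prf_k >= 1, n_terms >= 0,
            source_field %in% TEXT_FIELDS)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 prf_k = as.integer(prf_k), n_terms = as.integer(n_terms),
                 source_field = source_field),
            class = "rocchio_params")
}

#' Feedback sets for Rocchio
#'
#' @param relevant List of named numeric document vectors (the `dr` set).
#' @param irrelevant List of named numeric document vectors (the `dnr`
#'   set). Either set may be empty; their document ids must be disjoint.
#' @return An object of class `feedback_sets`.
#' @export
feedback_sets <- function(relevant = list(), irrelevant = list()) {
  if (length(intersect(names(relevant), names(irrelevant)))) {
    stop("relevant and irrelevant feedback sets must be disjoint", call. = FALSE)
  }
  structure(list(relevant = relevant, irrelevant = irrelevant),
            class = "feedback_sets")
}

sum_vectors <- function(vecs) {
  terms <- unique(unlist(lapply(vecs, names), use.names = FALSE))
  out <- stats::setNames(numeric(length(terms)), terms)
  for (v in vecs) if (length(v)) out[names(v)] <- out[names(v)] + v
  out
}

#' Rocchio vector combination
#'
#' Computes the combined vector coordinate-wise over the union vocabulary;
#' an empty feedback set contributes nothing (its term is dropped, not a
#' division by zero). Negative coordinates are clamped to 0 after the
#' combination.
#'
#' @param query_vector Named numeric vector (term weights of the query).
#' @param feedback A [feedback_sets()].
#' @param params A [rocchio_params()].
#' @return Named numeric vector over the union vocabulary (clamped at 0).
#' @export
rocchio_vector <- function(query_vector, feedback, params = rocchio_params()) {
  stopifnot(inherits(feedback, "feedback_sets"),
            inherits(params, "rocchio_params"))
  terms <- unique(c(names(query_vector),
                    unlist(lapply(feedback$relevant, names), use.names = FALSE),
                    unlist(lapply(feedback$irrelevant, names), use.names = FALSE)))
  q <- stats::setNames(numeric(length(terms)), terms)
  if (length(query_vector)) q[names(query_vector)] <- params$alpha * query_vector
  if (length(feedback$relevant)) {
    s <- sum_vectors(feedback$relevant)
    q[names(s)] <- q[names(s)] + params$beta / length(feedback$relevant) * s
  }
  if (length(feedback$irrelevant)) {
    s <- sum_vectors(feedback$irrelevant)
    q[names(s)] <- q[names(s)] - params$gamma / length(feedback$irrelevant) * s
  }
  pmax(q, 0)
}

#' Pseudo-relevance feedback sets
#'
#' Runs the unexpanded query, takes the top `prf_k` documents, and treats
#' their `source_field` vectors as the relevant set; the irrelevant set is
#' empty (pseudo-relevance semantics use positive feedback only).
#'
#' @param index A [build_index()] result.
#' @param query A [multifield_query()].
#' @param params A [rocchio_params()].
#' @return A [feedback_sets()]; empty when the initial run retrieves
#'   nothing.
#' @export
prf_feedback <- function(index, query, params = rocchio_params()) {
  initial <- search_index(query, index, top_n = params$prf_k)
  rel <- lapply(initial$doc_id, doc_vector, field = params$source_field,
                index = index)
  names(rel) <- initial$doc_id
  feedback_sets(relevant = rel, irrelevant = list())
}

#' Judgment-based (oracle) feedback sets
#'
#' Uses graded judgments directly: documents judged relevant or partially
#' relevant (grade >= 1) form the relevant set, documents judged irrelevant
#' (grade 0) the irrelevant set; unjudged entries (grade -1) are excluded.
#'
#' @param qrels A [qrels()] table.
#' @param query_id Query whose judgments to use (must be present).
#' @param index A [build_index()] result.
#' @param source_field Field whose vectors are used, default
#'   `"description"`.
#' @return A [feedback_sets()].
#' @export
oracle_feedback <- function(qrels, query_id, index,
                            source_field = "description") {
  qq <- qrels[qrels$query_id == query_id, , drop = FALSE]
  if (!nrow(qq)) stop("query_id not present in qrels: ", query_id, call. = FALSE)
  qq <- qq[qq$doc_id %in% index$doc_ids, , drop = FALSE]
  vecs_of <- function(ids) {
    v <- lapply(ids, doc_vector, field = source_field, index = index)
    names(v) <- ids
    v
  }
  feedback_sets(relevant = vecs_of(qq$doc_id[qq$grade >= 1]),
                irrelevant = vecs_of(qq$doc_id[qq$grade == 0]))
}

#' Select expansion terms from a combined vector
#'
#' Ranks terms absent from the original query by weight descending (ties:
#' lexicographic term order) and keeps the top `n_terms` with positive
#' weight.
#'
#' @param qprime Named numeric vector (e.g. from [rocchio_vector()]).
#' @param original_terms Terms of the unexpanded query (excluded).
#' @param n_terms Number of terms to keep (>= 0).
#' @param method Method tag recorded on the result.
#' @return An object of class `expanded_query`: `original_terms`, `terms`
#'   (character), `weights` (numeric, descending), `method`.
#' @export
select_expansion_terms <- function(qprime, original_terms, n_terms = 5,
                                   method = "rocchio_prf") {
  stopifnot(n_terms >= 0)
  qprime <- qprime[!(names(qprime) %in% original_terms)]
  qprime <- qprime[qprime > 0]
  if (length(qprime)) {
    ord <- order(-qprime, names(qprime), method = "radix")
    qprime <- qprime[ord][seq_len(min(n_terms, length(qprime)))]
  }
  if (n_terms == 0) qprime <- qprime[0]
  structure(list(original_terms = as.character(original_terms),
                 terms = names(qprime),
                 weights = unname(qprime),
                 method = method),
            class = "expanded_query")
}

#' @export
print.expanded_query <- function(x, ...) {
  cat("<expanded_query>", x$method, "\n")
  if (length(x$terms)) {
    cat(sprintf("  %s (%.4f)\n", x$terms, x$weights), sep = "")
  } else cat("  (no expansion terms)\n")
  invisible(x)
}

#' Rocchio expansion of a multi-field query
#'
#' Convenience wrapper: builds the query vector (term counts of the unique
#' analyzed query terms), obtains feedback (PRF or judgment-based),
#' combines with [rocchio_vector()] and selects the top expansion terms.
#'
#' @param query A [multifield_query()] (the unexpanded query).
#' @param index A [build_index()] result.
#' @param params A [rocchio_params()].
#' @param qrels Optional [qrels()]; when supplied together with `query_id`,
#'   judgment-based feedback is used instead of PRF.
#' @param query_id Query id for judgment-based feedback.
#' @return An `expanded_query`.
#' @export
rocchio_expand <- function(query, index, params = rocchio_params(),
                           qrels = NULL, query_id = NULL) {
  original <- unique(unlist(lapply(query$clauses, `[[`, "terms"),
                            use.names = FALSE))
  # the query vector weights each unique term once, regardless of how many
  # clauses repeat it
  qvec <- stats::setNames(rep(1, length(original)), original)
  if (is.null(qrels)) {
    fb <- prf_feedback(index, query, params)
    method <- "rocchio_prf"
  } else {
    fb <- oracle_feedback(qrels, query_id, index, params$source_field)
    method <- "rocchio_oracle"
  }
  qp <- rocchio_vector(qvec, fb, params)
  select_expansion_terms(qp, original, params$n_terms, method = method)
}

#' Lexicon-based expansion
#'
#' Collects the associated terms (canonical names and synonyms) of every
#' lexicon entry mentioned in the query, analyzes them, and ranks the
#' candidate terms by `idf` in `source_field` — frequent terms are of low
#' utility, rare terms of high utility. Original query terms are excluded.
#'
#' @param tagged A [tag_entities()] result.
#' @param lexicon The [biomed_lexicon()] used for tagging.
#' @param index A [build_index()] result (for idf).
#' @param source_field Field whose idf ranks candidates, default
#'   `"description"`.
#' @param n_terms Number of terms to keep, default 5.
#' @param config An [analyzer_config()].
#' @return An `expanded_query` with method `"lexicon"`.
#' @export
lexicon_expand <- function(tagged, lexicon, index,
                           source_field = "description", n_terms = 5,
                           config = analyzer_config()) {
  stopifnot(inherits(tagged, "tagged_query"))
  ids <- unique(tagged$mentions$entry_id)
  cand <- character(0)
  for (id in ids) {
    i <- match(id, lexicon$entry_id)
    phrases <- c(lexicon$canonical_name[i], lexicon$synonyms[[i]])
    cand <- c(cand, unlist(lapply(phrases, analyze, config = config),
                           use.names = FALSE))
  }
  cand <- setdiff(unique(cand), tagged$analyzed_terms)
  if (!length(cand)) {
    return(select_expansion_terms(stats::setNames(numeric(0), character(0)),
                                  tagged$analyzed_terms, n_terms,
                                  method = "lexicon"))
  }
  w <- stats::setNames(idf(cand, source_field, index), cand)
  select_expansion_terms(w, tagged$analyzed_terms, n_terms, method = "lexicon")
}

#' Apply expansion terms to a multi-field query
#'
#' Appends the expansion terms, unboosted, to the three always-on clauses
#' (`title`, `description`, `article_title`); entity- and field-specific
#' clauses are untouched. Terms already present in a clause are not
#' duplicated, so applying the same expansion twice is a no-op.
#'
#' @param query A [multifield_query()].
#' @param expanded An `expanded_query`.
#' @return A [multifield_query()].
#' @export
apply_expansion <- function(query, expanded) {
  stopifnot(inherits(query, "multifield_query"),
            inherits(expanded, "expanded_query"))
  if (!length(expanded$terms)) return(query)
  always_on <- c("title", "description", "article_title")
  query$clauses <- lapply(query$clauses, function(cl) {
    if (!(cl$field %in% always_on)) return(cl)
    add <- setdiff(expanded$terms, cl$terms)
    if (!length(add)) return(cl)
    query_clause(cl$field, c(cl$terms, add), boost = cl$boost,
                 term_boosts = c(cl$term_boosts, rep(1, length(add))))
  })
  query
}
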