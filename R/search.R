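#' Multi-field queries and vector-space scoring
#'
#' A query is a set of clauses, each targeting one field with a list of
#' analyzed terms and per-term boosts, plus an optional category filter.
#' Scoring follows the classic practical TF-IDF vector-space formula of the
#' Lucene engine family:
#'
#'   score(q, d) = coord(q, d) * sum over matching (clause, term) pairs of
#'                 sqrt(tf) * idf^2 * boost * 1/sqrt(field length)
#'
#' where coord is the fraction of (clause, term) pairs that match the
#' document. The per-query normalization constant is omitted: it is
#' identical for every document and therefore rank-invariant; the
#' field-length norm is the exact 1/sqrt(length), not a quantized
#' approximation.
#'
#' @name search
NULL

#' Create a query clause
#'
#' @param field Canonical text-field name to target.
#' @param terms Analyzed terms.
#' @param boost Clause-level boost (> 0), default 1.
#' @param term_boosts Optional numeric vector of per-term boosts (recycled
#'   scalar allowed); effective boost of a term is `boost * term_boost`.
#' @return An object of class `query_clause`.
#' @export
query_clause <- function(field, terms, boost = 1, term_boosts = 1) {
  stopifnot(field %in% TEXT_FIELDS, boost > 0, all(term_boosts > 0))
  terms <- as.character(terms)
  term_boosts <- rep_len(as.numeric(term_boosts), length(terms))
  structure(list(field = field, terms = terms, boost = as.numeric(boost),
                 term_boosts = term_boosts),
            class = "query_clause")
}

#' Create a multi-field query
#'
#' @param clauses List of [query_clause()]s (at least one).
#' @param category_filter Optional character vector of category labels; when
#'   set, only documents whose category is in the filter — or is
#'   `"Unspecified"`, which is always admitted — are candidates.
#' @return An object of class `multifield_query`.
#' @export
multifield_query <- function(clauses, category_filter = NULL) {
  if (inherits(clauses, "query_clause")) clauses <- list(clauses)
  stopifnot(length(clauses) >= 1,
            all(vapply(clauses, inherits, logical(1), "query_clause")))
  structure(list(clauses = clauses,
                 category_filter = if (is.null(category_filter)) NULL
                                   else as.character(category_filter)),
            class = "multifield_query")
}

#' @export
print.multifield_query <- function(x, ...) {
  cat(format_query(x), sep = "\n")
  invisible(x)
}

#' Render a query in a readable clause syntax
#'
#' @param query A [multifield_query()].
#' @return Character vector, one line per clause (plus the filter, if any).
#' @export
format_query <- function(query) {
  lines <- vapply(query$clauses, function(cl) {
    terms <- ifelse(cl$term_boosts != 1,
                    sprintf("%s^%g", cl$terms, cl$term_boosts),
                    cl$terms)
    boost <- if (cl$boost != 1) sprintf("^%g", cl$boost) else ""
    sprintf("%s:(%s)%s", cl$field, paste(terms, collapse = " "), boost)
  }, character(1))
  if (!is.null(query$category_filter)) {
    lines <- c(lines, sprintf("category:{%s}",
                              paste(query$category_filter, collapse = ", ")))
  }
  lines
}

# Core scorer: returns list(score = numeric(n_docs), candidates = logical).
# Disjunctive semantics: every posting of every (clause, term) pair
# contributes; coord multiplies at the end.
score_all <- function(query, index) {
  n <- index$n_docs
  acc <- numeric(n)
  matches <- numeric(n)
  total_pairs <- 0L
  for (cl in query$clauses) {
    fl <- index$fields[[cl$field]]
    inv_norm <- rep(0, n)
    has <- !is.na(fl$field_len) & fl$field_len > 0
    inv_norm[has] <- 1 / sqrt(fl$field_len[has])
    total_pairs <- total_pairs + length(cl$terms)
    for (j in seq_along(cl$terms)) {
      p <- fl$postings[[cl$terms[j]]]
      if (is.null(p)) next
      idf2 <- idf(cl$terms[j], cl$field, index)^2
      contrib <- sqrt(p$tf) * idf2 * cl$boost * cl$term_boosts[j] * inv_norm[p$doc]
      acc[p$doc] <- acc[p$doc] + contrib
      matches[p$doc] <- matches[p$doc] + 1
    }
  }
  if (total_pairs == 0) return(list(score = numeric(n), matches = matches))
  list(score = acc * matches / total_pairs, matches = matches)
}

#' Score one document against a query
#'
#' @param query A [multifield_query()].
#' @param doc_id Document identifier (must be indexed).
#' @param index A [build_index()] result.
#' @return Non-negative real; 0 when no query term matches.
#' @export
score_document <- function(query, doc_id, index) {
  pos <- doc_position(index, doc_id)
  score_all(query, index)$score[pos]
}

#' Rank documents against a multi-field query
#'
#' All documents with positive score — restricted by the category filter if
#' one is set, which always admits `"Unspecified"` documents — sorted by
#' score descending with ties broken by ascending `doc_id`, truncated to
#' `top_n`.
#'
#' @param query A [multifield_query()].
#' @param index A [build_index()] result.
#' @param top_n Maximum ranking length (>= 1), default 1000.
#' @param query_id Query identifier recorded in the ranking, default "q".
#' @param run_tag Run tag recorded in the ranking, default "biodatasearch".
#' @return A `run_ranking` data.frame with columns `query_id`, `doc_id`,
#'   `rank`, `score`, `tag`.
#' @export
search_index <- function(query, index, top_n = 1000, query_id = "q",
                         run_tag = "biodatasearch") {
  stopifnot(top_n >= 1)
  if (index$n_docs == 0) return(run_ranking(query_id, character(0), numeric(0), run_tag))
  sc <- score_all(query, index)$score
  keep <- sc > 0
  if (!is.null(query$category_filter)) {
    keep <- keep & (index$category %in% c(query$category_filter, "Unspecified"))
  }
  pos <- which(keep)
  if (!length(pos)) return(run_ranking(query_id, character(0), numeric(0), run_tag))
  ord <- pos[order(-sc[pos], index$doc_ids[pos], method = "radix")]
  ord <- ord[seq_len(min(top_n, length(ord)))]
  run_ranking(query_id, index$doc_ids[ord], sc[ord], run_tag)
}

#' Construct a run ranking
#'
#' @param query_id Query identifier.
#' @param doc_ids Ranked document identifiers (unique).
#' @param scores Non-increasing scores parallel to `doc_ids`.
#' @param tag Run tag.
#' @return A `run_ranking` data.frame.
#' @export
run_ranking <- function(query_id, doc_ids, scores, tag = "biodatasearch") {
  stopifnot(length(doc_ids) == length(scores), !anyDuplicated(doc_ids))
  df <- data.frame(query_id = rep(as.character(query_id), length(doc_ids)),
                   doc_id = as.character(doc_ids),
                   rank = seq_along(doc_ids),
                   score = as.numeric(scores),
                   tag = rep(as.character(tag), length(doc_ids)),
                   stringsAsFactors = FALSE)
  class(df) <- c("run_ranking", "data.frame")
  df
}
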