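# Independent reference implementations used as oracles. Everything here is
# written in the most literal way possible (explicit loops, no shared code
# with the package) so agreement is evidence, not tautology.

oracle_p_at_k <- function(ranked_ids, grades, k) {
  hits <- 0
  for (i in seq_len(k)) {
    if (i > length(ranked_ids)) break
    g <- grades[ranked_ids[i]]
    if (!is.na(g) && g >= 1) hits <- hits + 1
  }
  hits / k
}

oracle_recall <- function(ranked_ids, grades, cutoff) {
  R <- 0
  for (g in grades) if (g >= 1) R <- R + 1
  if (R == 0) return(NA_real_)
  hits <- 0
  for (i in seq_len(min(cutoff, length(ranked_ids)))) {
    g <- grades[ranked_ids[i]]
    if (!is.na(g) && g >= 1) hits <- hits + 1
  }
  hits / R
}

oracle_ap <- function(ranked_ids, grades) {
  R <- 0
  for (g in grades) if (g >= 1) R <- R + 1
  if (R == 0) return(NA_real_)
  total <- 0
  hits <- 0
  for (i in seq_along(ranked_ids)) {
    g <- grades[ranked_ids[i]]
    if (!is.na(g) && g >= 1) {
      hits <- hits + 1
      total <- total + hits / i
    }
  }
  total / R
}

oracle_ndcg <- function(ranked_ids, grades, k) {
  gain <- function(g) if (is.na(g) || g < 0) 0 else 2^g - 1
  dcg <- 0
  for (i in seq_len(min(k, length(ranked_ids)))) {
    dcg <- dcg + gain(grades[ranked_ids[i]]) / log2(i + 1)
  }
  ideal <- sort(vapply(grades, gain, numeric(1)), decreasing = TRUE)
  idcg <- 0
  for (i in seq_len(min(k, length(ideal)))) {
    idcg <- idcg + ideal[i] / log2(i + 1)
  }
  if (idcg == 0) return(NA_real_)
  unname(dcg / idcg)
}

# Brute-force multi-field scorer implementing the documented formula
# directly from the raw token lists of the records.
oracle_score <- function(query, record_tokens, all_tokens, doc_id) {
  n_docs <- length(all_tokens)
  total_pairs <- 0
  matches <- 0
  acc <- 0
  for (cl in query$clauses) {
    for (j in seq_along(cl$terms)) {
      total_pairs <- total_pairs + 1
      term <- cl$terms[j]
      toks <- record_tokens[[doc_id]][[cl$field]]
      if (is.null(toks) || length(toks) == 0) next
      tf <- sum(toks == term)
      if (tf == 0) next
      df <- 0
      for (d in seq_len(n_docs)) {
        dt <- all_tokens[[d]][[cl$field]]
        if (!is.null(dt) && any(dt == term)) df <- df + 1
      }
      idf_val <- 1 + log(n_docs / (df + 1))
      acc <- acc + sqrt(tf) * idf_val^2 * cl$boost * cl$term_boosts[j] /
        sqrt(length(toks))
      matches <- matches + 1
    }
  }
  if (total_pairs == 0) return(0)
  acc * matches / total_pairs
}

# Dense-vector Rocchio over an explicit term universe.
oracle_rocchio <- function(query_vector, relevant, irrelevant,
                           alpha, beta, gamma, universe) {
  out <- numeric(length(universe))
  names(out) <- universe
  for (t in universe) {
    v <- alpha * (if (t %in% names(query_vector)) query_vector[[t]] else 0)
    if (length(relevant) > 0) {
      s <- 0
      for (dv in relevant) s <- s + (if (t %in% names(dv)) dv[[t]] else 0)
      v <- v + beta * s / length(relevant)
    }
    if (length(irrelevant) > 0) {
      s <- 0
      for (dv in irrelevant) s <- s + (if (t %in% names(dv)) dv[[t]] else 0)
      v <- v - gamma * s / length(irrelevant)
    }
    out[[t]] <- max(0, v)
  }
  out
}

oracle_overlap <- function(x1, x2) {
  x1 <- unique(x1); x2 <- unique(x2)
  inter <- 0
  for (a in x1) if (a %in% x2) inter <- inter + 1
  inter / min(length(x1), length(x2))
}
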