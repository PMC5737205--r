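#' Retrieval evaluation: TREC formats, standard and inferred metrics
#'
#' Judgments are graded on a four-value scale: 2 (relevant), 1 (partially
#' relevant), 0 (irrelevant), -1 (unjudged). Binary metrics (P@k, Recall,
#' AP) treat grade >= 1 as relevant and everything else — including
#' unjudged — as non-relevant. Graded metrics use gain 2^grade - 1 with a
#' 1/log2(rank + 1) discount. Inferred metrics (infAP, infNDCG) estimate
#' their exact counterparts from a uniformly sampled subset of the
#' judgments and reduce to them exactly at a 100% sampling rate.
#'
#' @name evaluation
NULL

GRADE_SCALE <- c(-1, 0, 1, 2)

#' Construct a qrels table
#'
#' @param query_id,doc_id,grade Parallel vectors; `grade` must lie in
#'   \{2, 1, 0, -1\} with one grade per (query, document) pair.
#' @return data.frame of class `qrels`.
#' @export
qrels <- function(query_id, doc_id, grade) {
  grade <- as.integer(grade)
  if (!all(grade %in% GRADE_SCALE)) {
    stop("grades must be in {2, 1, 0, -1}", call. = FALSE)
  }
  df <- data.frame(query_id = as.character(query_id),
                   doc_id = as.character(doc_id),
                   grade = grade, stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("query_id", "doc_id")])) {
    stop("duplicate (query_id, doc_id) pair in qrels", call. = FALSE)
  }
  class(df) <- c("qrels", "data.frame")
  df
}

#' Read TREC-format qrels
#'
#' Four whitespace-separated columns: `query_id iter doc_id grade`.
#'
#' @param path File path.
#' @return A [qrels()] table.
#' @export
read_qrels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, integer(1)) != 4)
  if (length(bad)) {
    stop("malformed qrels line ", bad[1], ": expected 4 columns", call. = FALSE)
  }
  g <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 4)))
  badg <- which(is.na(g) | !(g %in% GRADE_SCALE))
  if (length(badg)) {
    stop("malformed qrels line ", badg[1], ": grade outside {2, 1, 0, -1}",
         call. = FALSE)
  }
  qrels(vapply(parts, `[[`, character(1), 1),
        vapply(parts, `[[`, character(1), 3), g)
}

#' Write TREC-format qrels
#'
#' @param x A [qrels()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(x, path) {
  writeLines(sprintf("%s 0 %s %d", x$query_id, x$doc_id, x$grade), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a TREC-format run file
#'
#' Six whitespace-separated columns: `query_id Q0 doc_id rank score tag`.
#' Rankings are re-sorted deterministically by score descending, then
#' doc_id ascending, and ranks are reassigned.
#'
#' @param path File path.
#' @return A `run_ranking` data.frame covering all queries in the file.
#' @export
read_run <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, integer(1)) != 6)
  if (length(bad)) {
    stop("malformed run line ", bad[1], ": expected 6 columns", call. = FALSE)
  }
  df <- data.frame(query_id = vapply(parts, `[[`, character(1), 1),
                   doc_id = vapply(parts, `[[`, character(1), 3),
                   score = as.numeric(vapply(parts, `[[`, character(1), 5)),
                   tag = vapply(parts, `[[`, character(1), 6),
                   stringsAsFactors = FALSE)
  if (anyNA(df$score)) {
    stop("malformed run line ", which(is.na(df$score))[1],
         ": non-numeric score", call. = FALSE)
  }
  pieces <- lapply(split(df, df$query_id), function(d) {
    d <- d[order(-d$score, d$doc_id, method = "radix"), , drop = FALSE]
    run_ranking(d$query_id[1], d$doc_id, d$score, d$tag[1])
  })
  out <- do.call(rbind, unname(pieces))
  class(out) <- c("run_ranking", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write a TREC-format run file
#'
#' @param run A `run_ranking` data.frame (one or more queries).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  writeLines(sprintf("%s Q0 %s %d %.6f %s", run$query_id, run$doc_id,
                     run$rank, run$score, run$tag),
             path, useBytes = TRUE)
  invisible(path)
}

# grades for one query as a named vector
query_grades <- function(qrels, query_id) {
  qq <- qrels[qrels$query_id == query_id, , drop = FALSE]
  stats::setNames(qq$grade, qq$doc_id)
}

gain_of <- function(grade) 2^pmax(grade, 0) - 1

#' Precision at k
#'
#' @param ranked_ids Ranked document ids for one query.
#' @param grades Named grade vector (judged docs for the query).
#' @param k Cutoff (>= 1). Rankings shorter than `k` are treated as padded
#'   with non-relevant documents (the divisor stays `k`).
#' @return Fraction of the first `k` positions holding a document with
#'   grade >= 1.
#' @export
precision_at_k <- function(ranked_ids, grades, k) {
  stopifnot(k >= 1)
  top <- ranked_ids[seq_len(min(k, length(ranked_ids)))]
  sum(grades[top] >= 1, na.rm = TRUE) / k
}

#' Recall at a cutoff
#'
#' @inheritParams precision_at_k
#' @param cutoff Ranking depth considered (0 allowed).
#' @return Fraction of the query's relevant documents (grade >= 1)
#'   retrieved within `cutoff`; `NA` with a warning when the query has no
#'   relevant documents.
#' @export
recall_at_cutoff <- function(ranked_ids, grades, cutoff = length(ranked_ids)) {
  R <- sum(grades >= 1)
  if (R == 0) {
    warning("query has no relevant documents; recall undefined")
    return(NA_real_)
  }
  if (cutoff == 0) return(0)
  top <- ranked_ids[seq_len(min(cutoff, length(ranked_ids)))]
  sum(grades[top] >= 1, na.rm = TRUE) / R
}

#' Average precision
#'
#' Mean over the query's relevant documents of the precision at their
#' retrieved ranks; relevant documents never retrieved contribute zero.
#'
#' @inheritParams precision_at_k
#' @return AP in [0, 1]; `NA` with a warning when the query has no
#'   relevant documents (such queries are excluded from MAP).
#' @export
average_precision <- function(ranked_ids, grades) {
  R <- sum(grades >= 1)
  if (R == 0) {
    warning("query has no relevant documents; AP undefined")
    return(NA_real_)
  }
  if (!length(ranked_ids)) return(0)
  is_rel <- !is.na(grades[ranked_ids]) & grades[ranked_ids] >= 1
  if (!any(is_rel)) return(0)
  ranks <- which(is_rel)
  sum(cumsum(is_rel)[ranks] / ranks) / R
}

#' Normalized discounted cumulative gain at k
#'
#' Gain 2^grade - 1 (unjudged counts 0), discount 1/log2(rank + 1). The
#' ideal ranking sorts the query's judged grades descending.
#'
#' @inheritParams precision_at_k
#' @param k Cutoff, default the ranking length.
#' @return NDCG in [0, 1]; `NA` with a warning when the ideal DCG is zero.
#' @export
ndcg_at_k <- function(ranked_ids, grades, k = length(ranked_ids)) {
  ideal_gain <- sort(gain_of(grades), decreasing = TRUE)
  ideal_gain <- ideal_gain[seq_len(min(k, length(ideal_gain)))]
  idcg <- sum(ideal_gain / log2(seq_along(ideal_gain) + 1))
  if (idcg == 0) {
    warning("query has ideal DCG 0; NDCG undefined")
    return(NA_real_)
  }
  top <- ranked_ids[seq_len(min(k, length(ranked_ids)))]
  g <- gain_of(grades[top])
  g[is.na(g)] <- 0
  sum(g / log2(seq_along(top) + 1)) / idcg
}

#' Inferred average precision from sampled judgments
#'
#' Expected-value estimator of AP when only a uniform sample of the
#' judgment pool is available. Each sampled relevant document at rank k
#' contributes an estimated precision-at-k in which the number of relevant
#' documents above k is scaled up by the inverse sampling rate; the mean is
#' taken over all sampled relevant documents. At `rate = 1` this is
#' exactly [average_precision()].
#'
#' @param ranked_ids Ranked document ids for one query.
#' @param sampled_grades Named grade vector of the *sampled* judgments
#'   (grades 2/1/0; unsampled pairs are simply absent).
#' @param rate Sampling rate in (0, 1].
#' @return Estimated AP in [0, 1]; `NA` with a warning when the sample
#'   contains no relevant document.
#' @export
inferred_ap <- function(ranked_ids, sampled_grades, rate) {
  stopifnot(rate > 0, rate <= 1)
  if (!length(sampled_grades)) {
    stop("no sampled judgments; infAP undefined", call. = FALSE)
  }
  rel_ids <- names(sampled_grades)[sampled_grades >= 1]
  if (!length(rel_ids)) {
    warning("sample contains no relevant document; infAP undefined")
    return(NA_real_)
  }
  ranks <- which(ranked_ids %in% rel_ids)
  if (!length(ranks)) return(0)
  srel_above <- seq_along(ranks) - 1
  est_p <- pmin(1, (1 + srel_above / rate) / ranks)
  min(1, sum(est_p) / length(rel_ids))
}

#' Inferred NDCG from sampled judgments
#'
#' The DCG of the sampled judged documents in the ranking, with each
#' contribution scaled by the inverse sampling rate, normalized by an
#' ideal DCG computed from the inverse-rate-scaled grade counts (with
#' fractional counts handled by positional interpolation). At `rate = 1`
#' this is exactly [ndcg_at_k()].
#'
#' @inheritParams inferred_ap
#' @param k Cutoff, default the ranking length.
#' @return Estimated NDCG in [0, 1]; `NA` with a warning when the
#'   estimated ideal DCG is zero.
#' @export
inferred_ndcg <- function(ranked_ids, sampled_grades, rate,
                          k = length(ranked_ids)) {
  stopifnot(rate > 0, rate <= 1)
  if (!length(sampled_grades)) {
    stop("no sampled judgments; infNDCG undefined", call. = FALSE)
  }
  top <- ranked_ids[seq_len(min(k, length(ranked_ids)))]
  g <- gain_of(sampled_grades[top])
  g[is.na(g)] <- 0
  dcg <- sum(g / log2(seq_along(top) + 1)) / rate
  n2 <- sum(sampled_grades == 2) / rate
  n1 <- sum(sampled_grades == 1) / rate
  n_pos <- min(k, ceiling(n2 + n1))
  if (n_pos == 0 || (n2 + n1) == 0) {
    warning("sample implies ideal DCG 0; infNDCG undefined")
    return(NA_real_)
  }
  i <- seq_len(n_pos)
  # fraction of position i covered by grade-2 mass, then grade-1 mass
  f2 <- pmax(0, pmin(i, n2) - (i - 1))
  f1 <- pmax(0, pmin(i, n2 + n1) - pmax(i - 1, n2))
  idcg <- sum((3 * f2 + 1 * f1) / log2(i + 1))
  if (idcg == 0) {
    warning("sample implies ideal DCG 0; infNDCG undefined")
    return(NA_real_)
  }
  max(0, min(1, dcg / idcg))
}

#' Overlap similarity of two term sets
#'
#' `Overlap(X1, X2) = |X1 n X2| / min(|X1|, |X2|)`.
#'
#' @param x1,x2 Character vectors (treated as sets; both non-empty).
#' @return Real in [0, 1].
#' @export
overlap_similarity <- function(x1, x2) {
  x1 <- unique(x1); x2 <- unique(x2)
  if (!length(x1) || !length(x2)) {
    stop("overlap similarity undefined for an empty set", call. = FALSE)
  }
  length(intersect(x1, x2)) / min(length(x1), length(x2))
}

# --- Aggregate reporting ---------------------------------------------------

#' Evaluate a run against qrels
#'
#' Computes per-query P@10, P@100, Recall, AP and NDCG, plus infAP and
#' infNDCG when sampled qrels with a sampling-rate sidecar are supplied.
#' Queries absent from the qrels are skipped with a warning; queries with
#' no relevant documents are excluded from the AP/Recall means.
#'
#' @param run A `run_ranking` data.frame (any number of queries).
#' @param qrels A [qrels()] table.
#' @param sampled Optional sampled [qrels()] for the inferred metrics.
#' @param sidecar Optional sampling sidecar (data.frame `query_id`,
#'   `stratum`, `rate`) accompanying `sampled`.
#' @return A `metric_report`: list with `per_query` (data.frame) and
#'   `means` (named numeric, arithmetic means over evaluated queries).
#' @export
evaluate_run <- function(run, qrels, sampled = NULL, sidecar = NULL) {
  qids <- unique(run$query_id)
  judged <- unique(qrels$query_id)
  missing <- setdiff(qids, judged)
  if (length(missing)) {
    warning("skipping ", length(missing), " quer",
            if (length(missing) == 1) "y" else "ies", " absent from qrels: ",
            paste(missing, collapse = ", "))
    qids <- intersect(qids, judged)
  }
  rows <- lapply(qids, function(qid) {
    ids <- run$doc_id[run$query_id == qid]
    g <- query_grades(qrels, qid)
    row <- data.frame(
      query_id = qid,
      p10 = precision_at_k(ids, g, 10),
      p100 = precision_at_k(ids, g, 100),
      recall = suppressWarnings(recall_at_cutoff(ids, g)),
      ap = suppressWarnings(average_precision(ids, g)),
      ndcg = suppressWarnings(ndcg_at_k(ids, g)),
      stringsAsFactors = FALSE)
    if (!is.null(sampled)) {
      sg <- query_grades(sampled, qid)
      sg <- sg[sg >= 0]
      rate <- 1
      if (!is.null(sidecar)) {
        r <- sidecar$rate[sidecar$query_id == qid]
        if (length(r)) rate <- r[1]
      }
      row$inf_ap <- if (length(sg)) {
        suppressWarnings(inferred_ap(ids, sg, rate))
      } else NA_real_
      row$inf_ndcg <- if (length(sg)) {
        suppressWarnings(inferred_ndcg(ids, sg, rate))
      } else NA_real_
    }
    row
  })
  per_query <- do.call(rbind, rows)
  means <- colMeans(per_query[, -1, drop = FALSE], na.rm = TRUE)
  structure(list(per_query = per_query, means = means),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> over", nrow(x$per_query), "queries\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Per-field overlap analysis between queries and judged documents
#'
#' For each query and each judged document at the requested grades,
#' computes the overlap similarity between the analyzed query term set and
#' the analyzed term set of each document field — the collection-level
#' diagnostic of how little query vocabulary reaches each metadata field.
#'
#' @param records List of [dataset_record()]s.
#' @param queries data.frame with columns `query_id`, `text`.
#' @param qrels A [qrels()] table.
#' @param grades Grades to include, default `c(1, 2)` (relevant and
#'   partially relevant).
#' @param config An [analyzer_config()].
#' @return data.frame with columns `query_id`, `doc_id`, `field`,
#'   `overlap`.
#' @export
overlap_by_field <- function(records, queries, qrels, grades = c(1, 2),
                             config = analyzer_config()) {
  ids <- vapply(records, `[[`, character(1), "doc_id")
  out <- list()
  for (i in seq_len(nrow(queries))) {
    qid <- queries$query_id[i]
    qterms <- unique(analyze(queries$text[i], config))
    if (!length(qterms)) next
    qq <- qrels[qrels$query_id == qid & qrels$grade %in% grades, , drop = FALSE]
    for (doc in qq$doc_id) {
      rec <- records[[match(doc, ids)]]
      if (is.null(rec)) next
      for (f in names(rec$fields)) {
        dterms <- unique(analyze(field_text(rec, f), config))
        if (!length(dterms)) next
        out[[length(out) + 1]] <- data.frame(
          query_id = qid, doc_id = doc, field = f,
          overlap = overlap_similarity(qterms, dterms),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(0), doc_id = character(0),
                      field = character(0), overlap = numeric(0)))
  }
  do.call(rbind, out)
}

#' Box-plot-style summary of per-field overlaps
#'
#' @param overlaps Output of [overlap_by_field()].
#' @return data.frame with per-field `n`, `min`, `q1`, `median`, `q3`,
#'   `max`, suitable for TSV export.
#' @export
overlap_stats <- function(overlaps) {
  fields <- sort(unique(overlaps$field))
  do.call(rbind, lapply(fields, function(f) {
    v <- overlaps$overlap[overlaps$field == f]
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(field = f, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5], stringsAsFactors = FALSE)
  }))
}

#' Read a query file
#'
#' Two tab-separated columns: `query_id`, `text`.
#'
#' @param path File path.
#' @return data.frame with columns `query_id`, `text`.
#' @export
read_queries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad)) stop("malformed query line ", bad[1], call. = FALSE)
  data.frame(query_id = vapply(parts, `[[`, character(1), 1),
             text = vapply(parts, function(p) paste(p[-1], collapse = "\t"),
                           character(1)),
             stringsAsFactors = FALSE)
}

#' Write a query file
#'
#' @param queries data.frame with columns `query_id`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_queries <- function(queries, path) {
  writeLines(sprintf("%s\t%s", queries$query_id, queries$text), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read/write a sampling sidecar
#'
#' Three tab-separated columns with header: `query_id`, `stratum`, `rate`.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_sidecar <- function(path) {
  df <- utils::read.delim(path, quote = "",
                          colClasses = c("character", "character", "numeric"))
  stopifnot(all(c("query_id", "stratum", "rate") %in% names(df)))
  df
}

#' @rdname read_sidecar
#' @param sidecar data.frame with columns `query_id`, `stratum`, `rate`.
#' @export
write_sidecar <- function(sidecar, path) {
  lines <- c("query_id\tstratum\trate",
             sprintf("%s\t%s\t%s", sidecar$query_id, sidecar$stratum,
                     format(sidecar$rate, digits = 15)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
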