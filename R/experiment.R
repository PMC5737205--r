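#' End-to-end experiment harness
#'
#' Wires the modules into the standard workflows: plain field baselines,
#' the entity-aware multi-field builder, and the builder combined with each
#' query-expansion method, producing one TREC run and one metric report per
#' variant.
#'
#' @name cli_app
NULL

#' Standard experiment variants
#'
#' The comparison set: a description-only baseline, a title+description
#' baseline, the multi-field builder, and the builder with Rocchio-PRF,
#' judgment-based Rocchio, and lexicon expansion.
#'
#' @return List of variant descriptors understood by [run_experiment()].
#' @export
default_variants <- function() {
  list(
    list(name = "baseline_description", type = "baseline",
         fields = "description"),
    list(name = "baseline_title_description", type = "baseline",
         fields = c("title", "description")),
    list(name = "builder", type = "builder"),
    list(name = "builder_rocchio_prf", type = "builder",
         expansion = "rocchio_prf"),
    list(name = "builder_rocchio_oracle", type = "builder",
         expansion = "rocchio_oracle"),
    list(name = "builder_lexicon", type = "builder", expansion = "lexicon")
  )
}

#' Field-ablation variants
#'
#' One baseline variant per single field and per unordered field pair —
#' the diagonal-plus-pairs grid used to ask which metadata fields are
#' worth querying.
#'
#' @param fields Fields to ablate over; defaults to the 9 analyzed text
#'   fields (9 singles + 36 pairs = 45 variants).
#' @return List of variant descriptors.
#' @export
ablation_variants <- function(fields = TEXT_FIELDS) {
  out <- lapply(fields, function(f) {
    list(name = paste0("ablate_", f), type = "baseline", fields = f)
  })
  if (length(fields) >= 2) {
    pairs <- utils::combn(fields, 2, simplify = FALSE)
    out <- c(out, lapply(pairs, function(p) {
      list(name = paste0("ablate_", p[1], "_", p[2]), type = "baseline",
           fields = p)
    }))
  }
  out
}

#' Run an experiment over a collection
#'
#' For every variant, builds the per-query queries, searches, evaluates
#' against the qrels, and (optionally) writes a TREC run file and a metric
#' TSV per variant. Identical inputs produce identical run files.
#'
#' @param collection List with `records`, `lexicon`, `queries`, `qrels`
#'   (as returned by [generate_collection()], or assembled from files).
#' @param variants List of variant descriptors; see [default_variants()].
#'   Each descriptor has `name`, `type` (`"baseline"` or `"builder"`),
#'   optional `fields` (baseline) and optional `expansion`
#'   (`"rocchio_prf"`, `"rocchio_oracle"`, `"lexicon"`).
#' @param index Optional pre-built [build_index()] result (rebuilt from
#'   `collection$records` when `NULL`).
#' @param out_dir Optional directory for `run_<variant>.txt` and
#'   `metrics_<variant>.tsv` files.
#' @param top_n Ranking depth, default 1000.
#' @param config An [analyzer_config()].
#' @param rocchio A [rocchio_params()].
#' @param rules A [category_rules()] table for the builder.
#' @param sampled,sidecar Optional sampled qrels + sidecar; adds inferred
#'   metrics to the reports.
#' @param concept_boost Builder concept boost, default 2.
#' @return List with `runs` (named list of `run_ranking`), `reports`
#'   (named list of `metric_report`), `expansions` (named list of
#'   per-query expansion term logs), and `summary` (data.frame of mean
#'   metrics per variant).
#' @export
run_experiment <- function(collection, variants = default_variants(),
                           index = NULL, out_dir = NULL, top_n = 1000,
                           config = analyzer_config(),
                           rocchio = rocchio_params(),
                           rules = default_category_rules(),
                           sampled = NULL, sidecar = NULL,
                           concept_boost = 2) {
  if (!length(variants)) {
    return(list(runs = list(), reports = list(), expansions = list(),
                summary = data.frame()))
  }
  if (is.null(index)) index <- build_index(collection$records, config)
  queries <- collection$queries
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  runs <- list(); reports <- list(); expansions <- list()
  for (variant in variants) {
    vruns <- list()
    vexp <- list()
    for (i in seq_len(nrow(queries))) {
      qid <- queries$query_id[i]
      text <- queries$text[i]
      if (identical(variant$type, "baseline")) {
        q <- baseline_query(text, fields = variant$fields, config = config)
      } else {
        tagged <- tag_entities(text, collection$lexicon, rules = rules,
                               config = config)
        q <- build_query(tagged, config = config,
                         concept_boost = concept_boost)
        if (!is.null(variant$expansion)) {
          exp <- switch(
            variant$expansion,
            rocchio_prf = rocchio_expand(q, index, rocchio),
            rocchio_oracle = rocchio_expand(q, index, rocchio,
                                            qrels = collection$qrels,
                                            query_id = qid),
            lexicon = lexicon_expand(tagged, collection$lexicon, index,
                                     source_field = rocchio$source_field,
                                     n_terms = rocchio$n_terms,
                                     config = config),
            stop("unknown expansion method: ", variant$expansion,
                 call. = FALSE))
          vexp[[qid]] <- exp
          q <- apply_expansion(q, exp)
        }
      }
      vruns[[i]] <- search_index(q, index, top_n = top_n, query_id = qid,
                                 run_tag = variant$name)
    }
    run <- do.call(rbind, vruns)
    class(run) <- c("run_ranking", "data.frame")
    report <- evaluate_run(run, collection$qrels, sampled = sampled,
                           sidecar = sidecar)
    runs[[variant$name]] <- run
    reports[[variant$name]] <- report
    if (length(vexp)) expansions[[variant$name]] <- vexp
    if (!is.null(out_dir)) {
      write_run(run, file.path(out_dir, paste0("run_", variant$name, ".txt")))
      pq <- report$per_query
      utils::write.table(
        rbind(pq, c(query_id = "all", as.list(report$means))),
        file.path(out_dir, paste0("metrics_", variant$name, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  summary <- do.call(rbind, lapply(names(reports), function(nm) {
    data.frame(variant = nm, t(reports[[nm]]$means), stringsAsFactors = FALSE)
  }))
  list(runs = runs, reports = reports, expansions = expansions,
       summary = summary)
}
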