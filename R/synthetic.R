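#' Seeded synthetic collections with planted graded relevance
#'
#' The generator emulates the structure of a multi-repository biomedical
#' dataset collection: repositories populate different subsets of the
#' canonical fields (field-presence heterogeneity), background text is
#' drawn from a Zipfian vocabulary, and entity names (genes, organisms,
#' diseases) come from a disjoint alphabet so planted relevance signal is
#' controllable. Each query mentions entities and topical terms; relevant
#' documents receive controlled term injection into their title,
#' description and entity fields, partially relevant documents a strict
#' subset, and judged irrelevant documents none.
#'
#' @name synthetic_data
NULL

default_repositories <- function() {
  list(
    list(name = "clintrials_like", category = "Clinical trials", n_docs = 350,
         fields = c("title", "description", "keywords", "diseases", "treatment")),
    list(name = "arrayexp_like", category = "Gene expression", n_docs = 450,
         fields = c("title", "description", "keywords", "organisms")),
    list(name = "pdb_like", category = "Protein structure", n_docs = 400,
         fields = c("title", "description", "keywords", "organisms", "genes"),
         pmids = TRUE),
    list(name = "proteome_like", category = "Proteomic data", n_docs = 200,
         fields = c("title", "keywords", "organisms")),
    list(name = "bioproject_like", category = "Unspecified", n_docs = 600,
         fields = c("title", "description", "keywords", "organisms"))
  )
}

#' Generator configuration
#'
#' Defaults give a 2,000-document, 5-repository, 20-query collection whose
#' full experimental harness runs in minutes on one CPU.
#'
#' @param seed Integer seed; identical configurations and seeds produce
#'   byte-identical serialized outputs.
#' @param repositories List of repository descriptors
#'   (`name`, `category`, `n_docs`, `fields`, optional `pmids`); the
#'   default emulates the field-presence heterogeneity of real aggregated
#'   collections, including one repository without a description field.
#' @param n_background Background vocabulary size (Zipf-distributed).
#' @param n_theme Size of the disjoint theme vocabulary from which
#'   per-query shared relevant-document terms are drawn.
#' @param n_genes,n_organisms,n_diseases Entity vocabulary sizes.
#' @param n_queries Number of queries.
#' @param n_rel2,n_rel1,n_nonrel Judged documents per query: relevant
#'   (grade 2), partially relevant (grade 1), irrelevant (grade 0).
#' @param n_distractors Unjudged documents per query that receive some of
#'   the query's topical terms but none of its entity or theme vocabulary,
#'   emulating the generality of keyword queries over a large collection.
#' @param n_topic_terms Query topical terms planted in full into grade-2
#'   titles/descriptions.
#' @param n_theme_terms Theme terms shared by a query's relevant
#'   descriptions (the vocabulary expansion should recover).
#' @param frac_category_queries Fraction of queries that carry a category
#'   key phrase (and hence a category filter).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             repositories = default_repositories(),
                             n_background = 800, n_theme = 300,
                             n_genes = 150, n_organisms = 150, n_diseases = 30,
                             n_queries = 20,
                             n_rel2 = 12, n_rel1 = 8, n_nonrel = 40,
                             n_distractors = 30,
                             n_topic_terms = 4, n_theme_terms = 6,
                             frac_category_queries = 0.4) {
  stopifnot(seed == as.integer(seed), n_queries >= 1,
            n_rel2 >= 1, n_rel1 >= 0, n_nonrel >= 0, n_distractors >= 0,
            n_topic_terms >= 1, n_theme_terms >= 0)
  structure(list(seed = as.integer(seed), repositories = repositories,
                 n_background = as.integer(n_background),
                 n_theme = as.integer(n_theme),
                 n_genes = as.integer(n_genes),
                 n_organisms = as.integer(n_organisms),
                 n_diseases = as.integer(n_diseases),
                 n_queries = as.integer(n_queries),
                 n_rel2 = as.integer(n_rel2), n_rel1 = as.integer(n_rel1),
                 n_nonrel = as.integer(n_nonrel),
                 n_distractors = as.integer(n_distractors),
                 n_topic_terms = as.integer(n_topic_terms),
                 n_theme_terms = as.integer(n_theme_terms),
                 frac_category_queries = frac_category_queries),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# Zipf-like token probabilities for background text. The rank shift mimics
# text that has already lost its stopword head: analyzed metadata has no
# tokens with double-digit percentage frequency, and without the shift the
# head tokens would act as synthetic stopwords that no analyzer removes.
zipf_probs <- function(n, s = 1.1, shift = 20) {
  p <- 1 / (seq_len(n) + shift)^s
  p / sum(p)
}

#' Generate a synthetic collection
#'
#' @param config A [generator_config()].
#' @return List with components `records` (list of [dataset_record()]s,
#'   literature fields already linked), `lexicon` ([biomed_lexicon()]),
#'   `queries` (data.frame `query_id`, `text`), `qrels` ([qrels()]),
#'   `articles` ([article_table()]).
#' @export
generate_collection <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n_total <- sum(vapply(config$repositories, `[[`, numeric(1), "n_docs"))
  n_judged <- config$n_rel2 + config$n_rel1 + config$n_nonrel +
    config$n_distractors
  if (config$n_queries * n_judged > n_total) {
    stop("infeasible config: more judged documents than documents available",
         call. = FALSE)
  }
  with_seed(config$seed, generate_collection_impl(config))
}

generate_collection_impl <- function(config) {
  background <- sprintf("w%04d", seq_len(config$n_background))
  bg_probs <- zipf_probs(config$n_background)
  theme_vocab <- sprintf("theme%03d", seq_len(config$n_theme))

  # entity lexicon: names drawn from an alphabet disjoint from background
  genes <- sprintf("GEN%03dX", seq_len(config$n_genes))
  gene_syn <- lapply(seq_len(config$n_genes),
                     function(i) c(sprintf("g%03dalt", i), sprintf("gprot%03d", i)))
  organisms <- sprintf("Orgus%03d breed%03d", seq_len(config$n_organisms),
                       seq_len(config$n_organisms))
  org_syn <- lapply(seq_len(config$n_organisms),
                    function(i) sprintf("obrev%03d", i))
  diseases <- sprintf("malady%02d", seq_len(config$n_diseases))
  dis_syn <- lapply(seq_len(config$n_diseases),
                    function(i) sprintf("dsyn%02d", i))
  lexicon <- biomed_lexicon(
    entry_id = c(sprintf("G%03d", seq_len(config$n_genes)),
                 sprintf("O%03d", seq_len(config$n_organisms)),
                 sprintf("D%03d", seq_len(config$n_diseases))),
    entity_type = rep(c("gene", "organism", "disease"),
                      c(config$n_genes, config$n_organisms, config$n_diseases)),
    canonical_name = c(genes, organisms, diseases),
    synonyms = c(gene_syn, org_syn, dis_syn))

  bg_text <- function(n) paste(sample(background, n, replace = TRUE,
                                      prob = bg_probs), collapse = " ")

  # --- base documents ------------------------------------------------------
  records <- list()
  pmid_pool <- character(0)
  articles_rows <- list()
  doc_no <- 0
  for (repo in config$repositories) {
    for (j in seq_len(repo$n_docs)) {
      doc_no <- doc_no + 1
      fields <- list()
      if ("title" %in% repo$fields) fields$title <- bg_text(8)
      if ("description" %in% repo$fields) fields$description <- bg_text(40)
      if ("keywords" %in% repo$fields) {
        fields$keywords <- replicate(4, bg_text(sample(1:2, 1)))
      }
      if ("organisms" %in% repo$fields) {
        fields$organisms <- sample(organisms, sample(1:2, 1))
      }
      if ("genes" %in% repo$fields) {
        fields$genes <- sample(genes, sample(1:2, 1))
      }
      if ("diseases" %in% repo$fields) {
        fields$diseases <- paste(sample(diseases, 1), bg_text(2))
      }
      if ("treatment" %in% repo$fields) fields$treatment <- bg_text(6)
      pmids <- character(0)
      if (isTRUE(repo$pmids)) {
        n_p <- sample(1:2, 1)
        pmids <- sprintf("p%05d", length(pmid_pool) + seq_len(n_p))
        pmid_pool <- c(pmid_pool, pmids)
        for (p in pmids) {
          articles_rows[[length(articles_rows) + 1]] <-
            data.frame(pmid = p, title = bg_text(10), abstract = bg_text(30),
                       stringsAsFactors = FALSE)
        }
      }
      records[[doc_no]] <- dataset_record(
        doc_id = sprintf("d%05d", doc_no), repository = repo$name,
        category = repo$category, fields = fields, pmids = pmids)
    }
  }
  categories <- vapply(records, `[[`, character(1), "category")

  # --- queries, planting, qrels -------------------------------------------
  cat_rules <- default_category_rules()
  plantable_cats <- c("Gene expression", "Protein structure", "Clinical trials")
  cat_phrase <- c("Gene expression" = "gene expression",
                  "Protein structure" = "protein structure",
                  "Clinical trials" = "clinical trial")
  n_cat_q <- round(config$frac_category_queries * config$n_queries)
  used <- rep(FALSE, length(records))
  queries <- list()
  qrels_rows <- list()
  # mid-frequency background terms make organic distractors without
  # swamping the planted signal
  topic_pool <- background[30:min(300, config$n_background)]
  # each query targets its own entities, so one query's planted documents
  # cannot masquerade as unjudged strong matches for another
  stopifnot(config$n_queries <= config$n_genes,
            config$n_queries <= config$n_organisms)
  gene_ids <- sample(config$n_genes, config$n_queries)
  org_ids <- sample(config$n_organisms, config$n_queries)
  stopifnot(config$n_queries * config$n_theme_terms <= config$n_theme)
  theme_slices <- matrix(sample(theme_vocab,
                                config$n_queries * config$n_theme_terms),
                         nrow = config$n_queries)

  for (qi in seq_len(config$n_queries)) {
    qid <- sprintf("q%02d", qi)
    topic <- sample(topic_pool, config$n_topic_terms)
    theme <- theme_slices[qi, ]
    gene_i <- gene_ids[qi]
    org_i <- org_ids[qi]
    category <- NULL
    if (qi <= n_cat_q) {
      category <- plantable_cats[1 + (qi - 1) %% length(plantable_cats)]
    }
    text <- paste0(
      "find ",
      if (!is.null(category)) paste0(cat_phrase[[category]], " data on ") else "data on ",
      paste(topic, collapse = " "), " for ", genes[gene_i],
      " in ", organisms[org_i])
    queries[[qi]] <- data.frame(query_id = qid, text = text,
                                stringsAsFactors = FALSE)

    # Relevant documents must survive the category filter, so they are
    # drawn from the query's category (or Unspecified); judged irrelevant
    # documents and unjudged topical distractors come from anywhere.
    eligible <- which(!used &
                        (if (is.null(category)) TRUE
                         else categories %in% c(category, "Unspecified")))
    n_rel <- config$n_rel2 + config$n_rel1
    if (length(eligible) < n_rel) {
      stop("infeasible config: not enough unjudged documents eligible for ",
           qid, call. = FALSE)
    }
    rel <- sample(eligible, n_rel)
    used[rel] <- TRUE
    rel2 <- rel[seq_len(config$n_rel2)]
    rel1 <- rel[config$n_rel2 + seq_len(config$n_rel1)]
    rest <- which(!used)
    n_rest <- config$n_nonrel + config$n_distractors
    if (length(rest) < n_rest) {
      stop("infeasible config: not enough unjudged documents left for ",
           qid, call. = FALSE)
    }
    picked <- sample(rest, n_rest)
    used[picked] <- TRUE
    nonrel <- picked[seq_len(config$n_nonrel)]
    distractors <- picked[config$n_nonrel + seq_len(config$n_distractors)]

    for (d in rel2) {
      rec <- records[[d]]
      # queries are general: each relevant document sees only part of the
      # query vocabulary, and the entity signal lives in the title and the
      # entity fields, with the lexicon synonym in the description
      if (!is.null(rec$fields$title)) {
        rec$fields$title <- paste(topic[1], genes[gene_i], rec$fields$title)
      }
      desc_inject <- paste(c(sample(topic, 2), theme, gene_syn[[gene_i]][1]),
                           collapse = " ")
      if (!is.null(rec$fields$description)) {
        rec$fields$description <- paste(desc_inject, rec$fields$description)
      } else if (!is.null(rec$fields$title)) {
        # repositories without a description still carry signal in the title
        rec$fields$title <- paste(paste(theme[1:2], collapse = " "),
                                  rec$fields$title)
      }
      if (!is.null(rec$fields$organisms)) {
        rec$fields$organisms <- unique(c(organisms[org_i], rec$fields$organisms))
      }
      if (!is.null(rec$fields$genes)) {
        rec$fields$genes <- unique(c(genes[gene_i], rec$fields$genes))
      }
      records[[d]] <- rec
    }
    # unjudged distractors about the same topic but not the same entities:
    # they emulate the generality of keyword queries over a large corpus
    for (d in distractors) {
      rec <- records[[d]]
      if (!is.null(rec$fields$title)) {
        rec$fields$title <- paste(topic[2], rec$fields$title)
      }
      if (!is.null(rec$fields$description)) {
        rec$fields$description <- paste(paste(sample(topic, 2), collapse = " "),
                                        rec$fields$description)
      }
      records[[d]] <- rec
    }
    # partially relevant: a strict subset of the planted vocabulary, in the
    # description only — poorly reachable by the original query, reachable
    # after expansion
    for (d in rel1) {
      rec <- records[[d]]
      sub_inject <- paste(c(topic[1], theme[seq_len(min(3, length(theme)))]),
                          collapse = " ")
      if (!is.null(rec$fields$description)) {
        rec$fields$description <- paste(sub_inject, rec$fields$description)
      } else if (!is.null(rec$fields$title)) {
        rec$fields$title <- paste(sub_inject, rec$fields$title)
      }
      # partially relevant documents study the right organism even though
      # their text barely overlaps the query
      if (!is.null(rec$fields$organisms)) {
        rec$fields$organisms <- unique(c(organisms[org_i], rec$fields$organisms))
      }
      records[[d]] <- rec
    }
    ids <- vapply(records, `[[`, character(1), "doc_id")
    qrels_rows[[qi]] <- data.frame(
      query_id = qid,
      doc_id = ids[c(rel2, rel1, nonrel)],
      grade = rep(c(2L, 1L, 0L),
                  c(length(rel2), length(rel1), length(nonrel))),
      stringsAsFactors = FALSE)
  }

  articles <- if (length(articles_rows)) {
    a <- do.call(rbind, articles_rows)
    article_table(a$pmid, a$title, a$abstract)
  } else {
    article_table(character(0), character(0), character(0))
  }
  records <- link_articles(records, articles)$records
  qr <- do.call(rbind, qrels_rows)
  list(records = records,
       lexicon = lexicon,
       queries = do.call(rbind, queries),
       qrels = qrels(qr$query_id, qr$doc_id, qr$grade),
       articles = articles)
}

#' Sample judgments uniformly
#'
#' Keeps each judged pair independently with probability `rate` and
#' records the rate in a sampling sidecar; `rate = 1` returns the
#' judgments unchanged.
#'
#' @param x A [qrels()] table.
#' @param rate Sampling rate in (0, 1].
#' @param seed Integer seed.
#' @return `list(qrels = <sampled qrels>, sidecar = <data.frame>)`.
#' @export
sample_judgments <- function(x, rate, seed = 1) {
  if (!(rate > 0 && rate <= 1)) {
    stop("sampling rate must lie in (0, 1]", call. = FALSE)
  }
  qids <- unique(x$query_id)
  sidecar <- data.frame(query_id = qids, stratum = "all", rate = rate,
                        stringsAsFactors = FALSE)
  if (rate == 1) return(list(qrels = x, sidecar = sidecar))
  keep <- with_seed(seed, stats::runif(nrow(x)) < rate)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qrels", "data.frame")
  list(qrels = out, sidecar = sidecar)
}
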