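#' Query understanding: categories, entities, and the multi-field builder
#'
#' Free-text queries are first inspected for the data category they target
#' (rule-based key phrases) and for mentions of biomedical entities (genes,
#' organisms, diseases) found by longest-match dictionary tagging against a
#' lexicon. The tagged query is then turned into a boosted multi-field
#' query: the title, description and article-title fields always receive
#' the full term set; entity mentions additionally target their dedicated
#' field, and concept terms are boosted.
#'
#' @name query_formulation
NULL

ENTITY_TYPES <- c("gene", "organism", "disease")

#' Build a biomedical lexicon
#'
#' @param entry_id Character vector of entry identifiers.
#' @param entity_type One of `"gene"`, `"organism"`, `"disease"` per entry.
#' @param canonical_name Canonical phrase per entry (non-empty).
#' @param synonyms List of character vectors (synonyms, acronyms, common
#'   denominations), one element per entry.
#' @return A data.frame of class `biomed_lexicon` with a `synonyms` list
#'   column.
#' @export
biomed_lexicon <- function(entry_id, entity_type, canonical_name,
                           synonyms = vector("list", length(entry_id))) {
  stopifnot(all(entity_type %in% ENTITY_TYPES), all(nzchar(canonical_name)),
            length(synonyms) == length(entry_id))
  df <- data.frame(entry_id = as.character(entry_id),
                   entity_type = as.character(entity_type),
                   canonical_name = as.character(canonical_name),
                   stringsAsFactors = FALSE)
  df$synonyms <- lapply(synonyms, function(s) as.character(s[nzchar(s)]))
  class(df) <- c("biomed_lexicon", "data.frame")
  df
}

#' Read a lexicon from TSV
#'
#' Expected columns: `entry_id`, `entity_type`, `canonical_name`,
#' `synonyms` (pipe-separated, possibly empty).
#'
#' @param path Path to the TSV file.
#' @return A [biomed_lexicon()].
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "")
  syn <- strsplit(df$synonyms, "|", fixed = TRUE)
  biomed_lexicon(df$entry_id, df$entity_type, df$canonical_name, syn)
}

#' Write a lexicon to TSV
#'
#' @param lexicon A [biomed_lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  syn <- vapply(lexicon$synonyms, paste, character(1), collapse = "|")
  lines <- c("entry_id\tentity_type\tcanonical_name\tsynonyms",
             sprintf("%s\t%s\t%s\t%s", lexicon$entry_id, lexicon$entity_type,
                     lexicon$canonical_name, syn))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Default category key-phrase rules
#'
#' Ordered first-match-wins rules relating key phrases in a query to the
#' data category it targets.
#'
#' @return data.frame of class `category_rules` with columns `phrase`
#'   (lowercase) and `category`.
#' @export
default_category_rules <- function() {
  category_rules(
    phrase = c("gene expression", "clinical trial", "protein structure",
               "protein sequencing", "proteomic data", "imaging data",
               "physiological signal", "phenotype"),
    category = c("Gene expression", "Clinical trials", "Protein structure",
                 "Protein structure", "Proteomic data", "Imaging data",
                 "Physiological signals", "Phenotype"))
}

#' Build a category rule set
#'
#' @param phrase Character vector of lowercase key phrases (ordered; the
#'   first matching rule wins).
#' @param category Parallel character vector of category labels.
#' @return data.frame of class `category_rules`.
#' @export
category_rules <- function(phrase, category) {
  stopifnot(length(phrase) == length(category), all(phrase == tolower(phrase)))
  df <- data.frame(phrase = as.character(phrase),
                   category = as.character(category), stringsAsFactors = FALSE)
  class(df) <- c("category_rules", "data.frame")
  df
}

normalize_ws <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

#' Identify the data category a query targets
#'
#' Case-insensitive substring match of each rule's key phrase against the
#' whitespace-normalized query; the first rule that fires decides.
#'
#' @param raw_text Query text.
#' @param rules A [category_rules()] table.
#' @return Category label, or `NULL` when no rule fires.
#' @export
identify_category <- function(raw_text, rules = default_category_rules()) {
  txt <- normalize_ws(raw_text)
  for (i in seq_len(nrow(rules))) {
    if (grepl(rules$phrase[i], txt, fixed = TRUE)) return(rules$category[i])
  }
  NULL
}

#' Tag entity mentions in a query
#'
#' Longest-match, case-insensitive dictionary tagging over canonical names
#' and synonyms: every occurrence of a lexicon phrase (on word boundaries)
#' is a candidate; overlapping shorter candidates are suppressed.
#'
#' @param raw_text Query text.
#' @param lexicon A [biomed_lexicon()].
#' @param rules Optional [category_rules()]; when supplied the tagged query
#'   also carries the identified category.
#' @param config An [analyzer_config()] for the analyzed term list.
#' @return An object of class `tagged_query`: `raw_text`,
#'   `analyzed_terms`, `mentions` (data.frame: `start`, `end`, `surface`,
#'   `entity_type`, `entry_id`), `category` (or `NULL`).
#' @export
tag_entities <- function(raw_text, lexicon, rules = NULL,
                         config = analyzer_config()) {
  stopifnot(inherits(lexicon, "biomed_lexicon"))
  cand <- list()
  if (nzchar(trimws(raw_text))) {
    for (i in seq_len(nrow(lexicon))) {
      phrases <- unique(c(lexicon$canonical_name[i], lexicon$synonyms[[i]]))
      for (ph in phrases) {
        if (!nzchar(ph)) next
        pat <- paste0("(?<![[:alnum:]])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", ph),
                      "(?![[:alnum:]])")
        m <- gregexpr(pat, raw_text, ignore.case = TRUE, perl = TRUE)[[1]]
        if (m[1] == -1) next
        for (k in seq_along(m)) {
          cand[[length(cand) + 1]] <- data.frame(
            start = m[k], end = m[k] + attr(m, "match.length")[k] - 1,
            surface = substr(raw_text, m[k], m[k] + attr(m, "match.length")[k] - 1),
            entity_type = lexicon$entity_type[i],
            entry_id = lexicon$entry_id[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    # longest match wins; ties by start position then entry order stability
    cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
    taken <- rep(FALSE, nchar(raw_text))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      span <- cand$start[i]:cand$end[i]
      if (!any(taken[span])) {
        keep[i] <- TRUE
        taken[span] <- TRUE
      }
    }
    mentions <- cand[keep, , drop = FALSE]
    mentions <- mentions[order(mentions$start), , drop = FALSE]
    rownames(mentions) <- NULL
  } else {
    mentions <- data.frame(start = integer(0), end = integer(0),
                           surface = character(0), entity_type = character(0),
                           entry_id = character(0), stringsAsFactors = FALSE)
  }
  structure(
    list(raw_text = raw_text,
         analyzed_terms = analyze(raw_text, config),
         mentions = mentions,
         category = if (is.null(rules)) NULL else identify_category(raw_text, rules)),
    class = "tagged_query"
  )
}

#' Build the boosted multi-field query from a tagged query
#'
#' Builder rules: the `title`, `description` and `article_title` fields are
#' always targeted with the full set of query terms; if organisms (genes)
#' are mentioned, the `organisms` (`genes`) field is additionally targeted
#' with the mention terms; concept terms identified in the query are
#' boosted by `concept_boost` everywhere they appear. The identified
#' category, if any, becomes the category filter. Disease mentions get the
#' concept boost but, by default, no dedicated `diseases` clause — the
#' sparsely and generically populated disease fields hurt retrieval.
#'
#' @param tagged A [tag_entities()] result with non-empty `analyzed_terms`.
#' @param config An [analyzer_config()].
#' @param concept_boost Boost factor for entity-mention terms, default 2.
#' @param disease_clause Also target the `diseases` field with disease
#'   mentions? Default `FALSE`.
#' @return A [multifield_query()].
#' @export
build_query <- function(tagged, config = analyzer_config(),
                        concept_boost = 2, disease_clause = FALSE) {
  stopifnot(inherits(tagged, "tagged_query"))
  terms <- tagged$analyzed_terms
  if (!length(terms)) stop("cannot build a query from an empty analyzed query",
                           call. = FALSE)
  mention_terms <- function(types) {
    m <- tagged$mentions[tagged$mentions$entity_type %in% types, , drop = FALSE]
    unique(unlist(lapply(m$surface, analyze, config = config), use.names = FALSE))
  }
  concept <- mention_terms(ENTITY_TYPES)
  tb <- ifelse(terms %in% concept, concept_boost, 1)
  clauses <- list(
    query_clause("title", terms, boost = 1, term_boosts = tb),
    query_clause("description", terms, boost = 1, term_boosts = tb),
    query_clause("article_title", terms, boost = 1, term_boosts = tb)
  )
  org <- mention_terms("organism")
  if (length(org)) {
    clauses[[length(clauses) + 1]] <-
      query_clause("organisms", org, boost = concept_boost)
  }
  gen <- mention_terms("gene")
  if (length(gen)) {
    clauses[[length(clauses) + 1]] <-
      query_clause("genes", gen, boost = concept_boost)
  }
  if (disease_clause) {
    dis <- mention_terms("disease")
    if (length(dis)) {
      clauses[[length(clauses) + 1]] <-
        query_clause("diseases", dis, boost = concept_boost)
    }
  }
  multifield_query(clauses, category_filter = tagged$category)
}

#' Build a plain baseline query over chosen fields
#'
#' The straightforward comparison run: every listed field is targeted with
#' the full analyzed term set, unboosted and unfiltered.
#'
#' @param raw_text Query text.
#' @param fields Fields to target, default `c("title", "description")`.
#' @param config An [analyzer_config()].
#' @return A [multifield_query()].
#' @export
baseline_query <- function(raw_text, fields = c("title", "description"),
                           config = analyzer_config()) {
  terms <- analyze(raw_text, config)
  if (!length(terms)) stop("cannot build a query from an empty analyzed query",
                           call. = FALSE)
  multifield_query(lapply(fields, query_clause, terms = terms))
}
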