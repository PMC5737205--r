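#' Per-field inverted index
#'
#' Each canonical text field gets its own postings so fields can be queried
#' and boosted independently. Alongside postings the index keeps the
#' per-(document, field) token counts needed for length normalization, the
#' document frequencies needed for idf, and the stored repository/category
#' labels used by the category filter.
#'
#' @name index
NULL

#' Build a fielded inverted index
#'
#' @param records List of [dataset_record()]s with unique `doc_id`s.
#' @param config An [analyzer_config()] applied identically to every field.
#' @return An object of class `fielded_index` with components:
#'   `n_docs`, `doc_ids`, `repository`, `category` (parallel to `doc_ids`),
#'   and `fields`, a named list holding for each field the forward term
#'   vectors (`docs`: list of named tf vectors by doc position), the
#'   postings (`postings`: term → list(doc = positions, tf = counts)),
#'   `df` (named integer) and `field_len` (numeric, `NA` where absent).
#' @export
build_index <- function(records, config = analyzer_config()) {
  doc_ids <- vapply(records, `[[`, character(1), "doc_id")
  if (anyDuplicated(doc_ids)) {
    stop("duplicate doc_id: ", doc_ids[duplicated(doc_ids)][1], call. = FALSE)
  }
  n <- length(records)
  fields <- list()
  for (f in TEXT_FIELDS) {
    docs <- vector("list", n)
    lens <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      txt <- field_text(records[[i]], f)
      if (is.null(txt)) next
      toks <- analyze(txt, config)
      lens[i] <- length(toks)
      if (length(toks)) {
        tf <- table(toks)
        docs[[i]] <- stats::setNames(as.integer(tf), names(tf))
      } else {
        docs[[i]] <- stats::setNames(integer(0), character(0))
      }
    }
    # invert the forward vectors into postings
    has <- which(!vapply(docs, is.null, logical(1)) &
                   vapply(docs, length, integer(1)) > 0)
    if (length(has)) {
      terms_all <- unlist(lapply(has, function(i) names(docs[[i]])), use.names = FALSE)
      docs_all <- rep(has, vapply(has, function(i) length(docs[[i]]), integer(1)))
      tf_all <- unlist(lapply(has, function(i) unname(docs[[i]])), use.names = FALSE)
      idx_by_term <- split(seq_along(terms_all), terms_all)
      postings <- lapply(idx_by_term, function(ii) {
        list(doc = docs_all[ii], tf = tf_all[ii])
      })
      df <- vapply(postings, function(p) length(unique(p$doc)), integer(1))
    } else {
      postings <- list()
      df <- stats::setNames(integer(0), character(0))
    }
    fields[[f]] <- list(docs = docs, postings = postings, df = df,
                        field_len = lens)
  }
  structure(
    list(n_docs = n,
         doc_ids = doc_ids,
         repository = vapply(records, `[[`, character(1), "repository"),
         category = vapply(records, `[[`, character(1), "category"),
         fields = fields,
         analyzer = config),
    class = "fielded_index"
  )
}

#' @export
print.fielded_index <- function(x, ...) {
  cat("<fielded_index>", x$n_docs, "documents\n")
  for (f in TEXT_FIELDS) {
    cat(sprintf("  %-17s vocab %6d, docs %d\n", f,
                length(x$fields[[f]]$df),
                sum(!is.na(x$fields[[f]]$field_len))))
  }
  invisible(x)
}

doc_position <- function(index, doc_id) {
  pos <- match(doc_id, index$doc_ids)
  if (is.na(pos)) stop("unknown doc_id: ", doc_id, call. = FALSE)
  pos
}

#' Document frequency of a term in a field
#'
#' @param term Analyzed term.
#' @param field Canonical text-field name.
#' @param index A [build_index()] result.
#' @return Integer count of documents whose `field` contains `term` (0 for
#'   unseen terms).
#' @export
doc_freq <- function(term, field, index) {
  d <- index$fields[[field]]$df[term]
  if (is.na(d)) 0L else as.integer(d)
}

#' Inverse document frequency
#'
#' The classic practical form `1 + ln(N / (df + 1))`; defined for unseen
#' terms (`df = 0`) and never negative for `df <= N - 1`.
#'
#' @inheritParams doc_freq
#' @return Non-negative real.
#' @export
idf <- function(term, field, index) {
  if (index$n_docs == 0) {
    stop("idf undefined on an empty index (N = 0)", call. = FALSE)
  }
  df <- vapply(term, doc_freq, integer(1), field = field, index = index)
  unname(1 + log(index$n_docs / (df + 1)))
}

#' TF-IDF document vector for one field
#'
#' Raw term frequency times idf; these are the document vectors that feed
#' the Rocchio feedback combination.
#'
#' @param doc_id Document identifier.
#' @param field Canonical text-field name.
#' @param index A [build_index()] result.
#' @return Named numeric vector (term → weight); empty if the field is
#'   absent or empty for this document.
#' @export
doc_vector <- function(doc_id, field, index) {
  pos <- doc_position(index, doc_id)
  tf <- index$fields[[field]]$docs[[pos]]
  if (is.null(tf) || !length(tf)) return(stats::setNames(numeric(0), character(0)))
  w <- as.numeric(tf) * idf(names(tf), field, index)
  stats::setNames(w, names(tf))
}

# --- Statistics dump and persistence --------------------------------------

#' Index statistics as deterministic TSV text
#'
#' Dumps N, per-field vocabulary sizes, and the full df table in sorted
#' order, so two indexes built from identical inputs dump byte-identically.
#'
#' @param index A [build_index()] result.
#' @return Character vector of TSV lines.
#' @export
index_stats <- function(index) {
  lines <- c("stat\tfield\tterm\tvalue",
             sprintf("n_docs\t-\t-\t%d", index$n_docs))
  for (f in TEXT_FIELDS) {
    fl <- index$fields[[f]]
    lines <- c(lines, sprintf("vocab_size\t%s\t-\t%d", f, length(fl$df)))
  }
  for (f in TEXT_FIELDS) {
    df <- index$fields[[f]]$df
    if (!length(df)) next
    ord <- order(names(df), method = "radix")
    lines <- c(lines, sprintf("df\t%s\t%s\t%d", f, names(df)[ord],
                              as.integer(df[ord])))
  }
  lines
}

#' Persist an index to a directory
#'
#' Layout: `labels.tsv` (doc_id, repository, category), and per field
#' `postings_<field>.tsv` (term, doc_id, tf) plus `lengths_<field>.tsv`
#' (doc_id, length). All files are sorted, so the layout is deterministic.
#'
#' @param index A [build_index()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("doc_id\trepository\tcategory",
               sprintf("%s\t%s\t%s", index$doc_ids, index$repository,
                       index$category)),
             file.path(dir, "labels.tsv"), useBytes = TRUE)
  for (f in TEXT_FIELDS) {
    fl <- index$fields[[f]]
    rows <- character(0)
    if (length(fl$postings)) {
      terms <- sort(names(fl$postings), method = "radix")
      rows <- unlist(lapply(terms, function(tm) {
        p <- fl$postings[[tm]]
        ord <- order(p$doc)
        sprintf("%s\t%s\t%d", tm, index$doc_ids[p$doc[ord]], p$tf[ord])
      }), use.names = FALSE)
    }
    writeLines(c("term\tdoc_id\ttf", rows),
               file.path(dir, paste0("postings_", f, ".tsv")), useBytes = TRUE)
    has <- which(!is.na(fl$field_len))
    writeLines(c("doc_id\tlength",
                 sprintf("%s\t%d", index$doc_ids[has], as.integer(fl$field_len[has]))),
               file.path(dir, paste0("lengths_", f, ".tsv")), useBytes = TRUE)
  }
  writeLines(index_stats(index), file.path(dir, "stats.tsv"), useBytes = TRUE)
  invisible(dir)
}

#' Read an index persisted by [write_index()]
#'
#' @param dir Directory written by [write_index()].
#' @return A `fielded_index`.
#' @export
read_index <- function(dir) {
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              colClasses = "character", quote = "")
  doc_ids <- labels$doc_id
  n <- length(doc_ids)
  fields <- list()
  for (f in TEXT_FIELDS) {
    po <- utils::read.delim(file.path(dir, paste0("postings_", f, ".tsv")),
                            colClasses = c("character", "character", "integer"),
                            quote = "")
    le <- utils::read.delim(file.path(dir, paste0("lengths_", f, ".tsv")),
                            colClasses = c("character", "integer"), quote = "")
    lens <- rep(NA_real_, n)
    lens[match(le$doc_id, doc_ids)] <- le$length
    docs <- vector("list", n)
    for (i in match(le$doc_id, doc_ids)) {
      docs[[i]] <- stats::setNames(integer(0), character(0))
    }
    if (nrow(po)) {
      pos <- match(po$doc_id, doc_ids)
      by_term <- split(seq_len(nrow(po)), po$term)
      postings <- lapply(by_term, function(ii) list(doc = pos[ii], tf = po$tf[ii]))
      df <- vapply(postings, function(p) length(unique(p$doc)), integer(1))
      by_doc <- split(seq_len(nrow(po)), pos)
      for (d in names(by_doc)) {
        ii <- by_doc[[d]]
        docs[[as.integer(d)]] <- stats::setNames(po$tf[ii], po$term[ii])
      }
    } else {
      postings <- list()
      df <- stats::setNames(integer(0), character(0))
    }
    fields[[f]] <- list(docs = docs, postings = postings, df = df,
                        field_len = lens)
  }
  structure(
    list(n_docs = n, doc_ids = doc_ids,
         repository = labels$repository, category = labels$category,
         fields = fields, analyzer = analyzer_config()),
    class = "fielded_index"
  )
}
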