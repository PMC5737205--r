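#' Dataset metadata records and heterogeneous-repository parsing
#'
#' A collection aggregates dataset descriptions from several repositories,
#' each exposing a different subset of a closed, 11-name field vocabulary.
#' A declarative schema registry maps repository-specific document paths to
#' the canonical field names and assigns each repository a data category
#' (e.g. "Gene expression", "Protein structure", "Unspecified").
#'
#' @name corpus
NULL

# The closed field vocabulary: 9 analyzed text fields plus the two stored
# labels (repository, category) that support filtering.
TEXT_FIELDS <- c("title", "description", "keywords", "organisms",
                 "article_title", "article_abstract", "genes", "diseases",
                 "treatment")
LABEL_FIELDS <- c("repository", "category")
CANONICAL_FIELDS <- c(TEXT_FIELDS, LABEL_FIELDS)
# Fields stored as lists of phrases in the canonical format; they are
# space-joined only at analysis time so phrase boundaries survive for
# dictionary tagging.
MULTI_FIELDS <- c("keywords", "organisms", "genes")

#' Canonical field names
#'
#' @return Character vector of the 11 canonical field names (9 analyzed
#'   text fields plus the stored `repository` and `category` labels).
#' @export
canonical_fields <- function() CANONICAL_FIELDS

#' Construct a dataset record
#'
#' @param doc_id Unique non-empty identifier.
#' @param repository Repository name.
#' @param category Data-category label; defaults to `"Unspecified"`.
#' @param fields Named list of text fields. Only canonical text-field names
#'   are allowed; multi-valued fields (`keywords`, `organisms`, `genes`)
#'   hold character vectors of phrases. Absent fields are simply absent,
#'   never empty-string placeholders.
#' @param pmids Character vector of linked article identifiers (may be empty).
#' @return An object of class `dataset_record`.
#' @export
dataset_record <- function(doc_id, repository, category = "Unspecified",
                           fields = list(), pmids = character(0)) {
  if (!is.character(doc_id) || length(doc_id) != 1 || !nzchar(doc_id)) {
    stop("doc_id must be a non-empty string", call. = FALSE)
  }
  bad <- setdiff(names(fields), TEXT_FIELDS)
  if (length(bad)) {
    stop("unknown field name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  # drop empty placeholders so field-presence statistics stay honest
  keep <- vapply(fields, function(v) {
    v <- v[!is.na(v) & nzchar(trimws(v))]
    length(v) > 0
  }, logical(1))
  fields <- fields[keep]
  fields <- lapply(fields, function(v) as.character(v[!is.na(v) & nzchar(trimws(v))]))
  structure(
    list(doc_id = doc_id,
         repository = as.character(repository),
         category = as.character(category),
         fields = fields,
         pmids = as.character(pmids)),
    class = "dataset_record"
  )
}

#' @export
print.dataset_record <- function(x, ...) {
  cat("<dataset_record>", x$doc_id, "\n")
  cat("  repository:", x$repository, " category:", x$category, "\n")
  cat("  fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

#' Field text joined for analysis
#'
#' Multi-valued fields are stored as phrase lists; indexing needs a single
#' string per field.
#'
#' @param record A [dataset_record()].
#' @param field Canonical text-field name.
#' @return A single string, or `NULL` if the field is absent.
#' @export
field_text <- function(record, field) {
  v <- record$fields[[field]]
  if (is.null(v)) return(NULL)
  paste(v, collapse = " ")
}

# --- Schema registry -------------------------------------------------------

#' Build a schema registry
#'
#' A registry entry per repository gives its category label and a mapping
#' from canonical field names to paths in that repository's raw documents
#' (path components separated by `/`). Reserved mapping keys: `doc_id`
#' (required) and `pmids` (optional).
#'
#' @param repositories Named list; each element is
#'   `list(category = <label>, fields = list(<canonical> = <path>, ...))`.
#' @return An object of class `schema_registry`.
#' @seealso [read_schema_registry()] for loading from YAML.
#' @export
schema_registry <- function(repositories) {
  stopifnot(is.list(repositories), length(names(repositories)) == length(repositories))
  for (repo in names(repositories)) {
    entry <- repositories[[repo]]
    if (is.null(entry$category) || length(entry$category) != 1) {
      stop("repository '", repo, "' must map to exactly one category", call. = FALSE)
    }
    mapped <- setdiff(names(entry$fields), c("doc_id", "pmids"))
    bad <- setdiff(mapped, TEXT_FIELDS)
    if (length(bad)) {
      stop("repository '", repo, "' maps non-canonical field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!"doc_id" %in% names(entry$fields)) {
      stop("repository '", repo, "' schema lacks a doc_id path", call. = FALSE)
    }
  }
  structure(list(repositories = repositories), class = "schema_registry")
}

#' Read a schema registry from a YAML file
#'
#' @param path Path to a YAML file with a top-level `repositories` map.
#' @return A [schema_registry()].
#' @export
read_schema_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema_registry(cfg$repositories)
}

# Navigate a parsed JSON/XML tree along "A/B/C". Returns a character vector
# of all leaf values found (multi-valued nodes yield several), or NULL.
tree_path <- function(tree, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  nodes <- list(tree)
  for (p in parts) {
    nxt <- list()
    for (nd in nodes) {
      if (!is.list(nd)) next
      hits <- which(names(nd) == p)
      for (h in hits) nxt[[length(nxt) + 1]] <- nd[[h]]
    }
    nodes <- nxt
    if (!length(nodes)) return(NULL)
  }
  vals <- unlist(lapply(nodes, function(nd) {
    if (is.list(nd)) unlist(nd, use.names = FALSE) else nd
  }), use.names = FALSE)
  vals <- as.character(vals)
  vals <- vals[!is.na(vals) & nzchar(trimws(vals))]
  if (!length(vals)) NULL else vals
}

#' Parse a raw repository document into a dataset record
#'
#' @param raw_document A parsed document tree: a nested list (from JSON) or
#'   an `xml2` document/node (converted internally).
#' @param registry A [schema_registry()].
#' @param repository Repository name; must be registered.
#' @return A [dataset_record()] with the category taken from the registry
#'   and only the fields the repository's schema provides.
#' @export
parse_record <- function(raw_document, registry, repository) {
  stopifnot(inherits(registry, "schema_registry"))
  entry <- registry$repositories[[repository]]
  if (is.null(entry)) {
    stop("unknown repository: ", repository, call. = FALSE)
  }
  if (inherits(raw_document, "xml_document") || inherits(raw_document, "xml_node")) {
    raw_document <- xml2::as_list(raw_document)
    # unwrap the single root element so schema paths start below it
    if (is.list(raw_document) && length(raw_document) == 1) {
      raw_document <- raw_document[[1]]
    }
  }
  paths <- entry$fields
  doc_id <- tree_path(raw_document, paths$doc_id)
  if (is.null(doc_id)) {
    stop("malformed record: missing DocID at path '", paths$doc_id,
         "' for repository ", repository, call. = FALSE)
  }
  fields <- list()
  for (fname in intersect(names(paths), TEXT_FIELDS)) {
    vals <- tree_path(raw_document, paths[[fname]])
    if (is.null(vals)) next
    if (!(fname %in% MULTI_FIELDS)) vals <- paste(vals, collapse = " ")
    fields[[fname]] <- vals
  }
  pmids <- character(0)
  if (!is.null(paths$pmids)) {
    p <- tree_path(raw_document, paths$pmids)
    if (!is.null(p)) pmids <- p
  }
  dataset_record(doc_id = doc_id[[1]], repository = repository,
                 category = entry$category, fields = fields, pmids = pmids)
}

# --- Article linkage -------------------------------------------------------

#' Read a PMID-to-article table
#'
#' @param path Path to a 3-column TSV with header `pmid`, `title`,
#'   `abstract`.
#' @return A data.frame of class `article_table`.
#' @export
read_article_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "")
  stopifnot(all(c("pmid", "title", "abstract") %in% names(df)))
  article_table(df$pmid, df$title, df$abstract)
}

#' Build a PMID-to-article table
#'
#' @param pmid,title,abstract Parallel character vectors.
#' @return A data.frame of class `article_table`.
#' @export
article_table <- function(pmid, title, abstract) {
  stopifnot(all(nzchar(pmid)))
  df <- data.frame(pmid = as.character(pmid), title = as.character(title),
                   abstract = as.character(abstract),
                   stringsAsFactors = FALSE)
  class(df) <- c("article_table", "data.frame")
  df
}

#' Populate literature fields from linked articles
#'
#' For every record with at least one PMID found in the table, fills
#' `article_title` and `article_abstract` with the concatenation of all
#' linked titles/abstracts in ascending PMID order. Lookup misses are
#' silent and counted.
#'
#' @param records List of [dataset_record()]s.
#' @param articles An [article_table()].
#' @param pmids_per_record Optional named list (by `doc_id`) overriding each
#'   record's own `pmids`.
#' @return `list(records = <updated list>, stats = <data.frame>)` where
#'   `stats` counts linked and missing PMIDs per record.
#' @export
link_articles <- function(records, articles, pmids_per_record = NULL) {
  stopifnot(inherits(articles, "article_table"))
  lut <- split(seq_len(nrow(articles)), articles$pmid)
  n_hit <- integer(length(records))
  n_miss <- integer(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    pmids <- if (!is.null(pmids_per_record)) {
      as.character(pmids_per_record[[rec$doc_id]])
    } else {
      rec$pmids
    }
    if (!length(pmids)) next
    pmids <- sort(unique(pmids))  # ascending PMID order: deterministic concat
    hit <- pmids %in% names(lut)
    n_hit[i] <- sum(hit)
    n_miss[i] <- sum(!hit)
    if (!any(hit)) next
    rows <- unlist(lut[pmids[hit]], use.names = FALSE)
    rec$fields$article_title <- paste(articles$title[rows], collapse = " ")
    rec$fields$article_abstract <- paste(articles$abstract[rows], collapse = " ")
    records[[i]] <- rec
  }
  stats <- data.frame(
    doc_id = vapply(records, `[[`, character(1), "doc_id"),
    linked = n_hit, missing = n_miss, stringsAsFactors = FALSE)
  list(records = records, stats = stats)
}

# --- Canonical JSON-lines I/O ---------------------------------------------

record_to_json <- function(rec) {
  obj <- list(doc_id = jsonlite::unbox(rec$doc_id),
              repository = jsonlite::unbox(rec$repository),
              category = jsonlite::unbox(rec$category))
  flds <- list()
  for (f in TEXT_FIELDS) {          # fixed key order for byte determinism
    v <- rec$fields[[f]]
    if (is.null(v)) next
    flds[[f]] <- if (f %in% MULTI_FIELDS) v else jsonlite::unbox(v)
  }
  obj$fields <- flds
  if (length(rec$pmids)) obj$pmids <- rec$pmids
  jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
}

#' Write a collection as canonical JSON lines
#'
#' One JSON document per line, fixed key order, so identical collections
#' serialize byte-identically.
#'
#' @param records List of [dataset_record()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_collection <- function(records, path) {
  ids <- vapply(records, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) stop("duplicate doc_id in collection", call. = FALSE)
  lines <- vapply(records, function(r) as.character(record_to_json(r)), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a canonical JSON-lines collection
#'
#' @param path Path written by [write_collection()].
#' @return List of [dataset_record()]s.
#' @export
read_collection <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  records <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    fields <- obj$fields
    if (is.null(fields)) fields <- list()
    fields <- lapply(fields, as.character)
    dataset_record(doc_id = obj$doc_id, repository = obj$repository,
                   category = obj$category, fields = fields,
                   pmids = if (is.null(obj$pmids)) character(0) else as.character(obj$pmids))
  })
  ids <- vapply(records, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) stop("duplicate doc_id in collection", call. = FALSE)
  records
}

#' Field-presence census
#'
#' Counts, per repository, how many records carry each canonical text
#' field — the collection-heterogeneity summary that motivates fielded
#' indexing.
#'
#' @param records List of [dataset_record()]s.
#' @return data.frame with columns `repository`, `field`, `n_present`,
#'   `n_docs`.
#' @export
field_census <- function(records) {
  repos <- vapply(records, `[[`, character(1), "repository")
  out <- list()
  for (repo in sort(unique(repos))) {
    rs <- records[repos == repo]
    for (f in TEXT_FIELDS) {
      n <- sum(vapply(rs, function(r) !is.null(r$fields[[f]]), logical(1)))
      out[[length(out) + 1]] <- data.frame(
        repository = repo, field = f, n_present = n, n_docs = length(rs),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
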