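#' Text analysis for indexing and querying
#'
#' Queries and record fields go through the same analysis chain before they
#' meet the index: lowercasing, tokenization on non-alphanumeric characters,
#' stopword removal and stemming. The chain is deterministic, so the same
#' configuration and text always produce the same token list.
#'
#' @name analyzer
NULL

#' Classic 33-word English stopword list
#'
#' The compact stopword list popularized by the standard analyzer of the
#' Lucene engine family: articles, conjunctions and a handful of function
#' words. Small on purpose — biomedical symbols such as gene names must not
#' be at risk of removal.
#'
#' @return Character vector of 33 lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "but", "by",
    "for", "if", "in", "into", "is", "it", "no", "not", "of",
    "on", "or", "such", "that", "the", "their", "then", "there",
    "these", "they", "this", "to", "was", "will", "with")
}

#' Create an analyzer configuration
#'
#' @param stopwords Character vector of lowercase stopwords. Defaults to
#'   [default_stopwords()].
#' @param stemmer `"porter"` (default) or `"none"`.
#' @param lowercase Lowercase the text before tokenizing? Default `TRUE`.
#' @return An object of class `analyzer_config`.
#' @examples
#' analyze("The structure of proteins", analyzer_config())
#' @export
analyzer_config <- function(stopwords = default_stopwords(),
                            stemmer = c("porter", "none"),
                            lowercase = TRUE) {
  stemmer <- match.arg(stemmer)
  structure(
    list(stopwords = as.character(stopwords),
         stemmer = stemmer,
         lowercase = isTRUE(lowercase)),
    class = "analyzer_config"
  )
}

#' Analyze text into index terms
#'
#' Tokenizes on maximal runs of letters/digits (so hyphenated gene symbols
#' split but alphanumeric symbols like "BeF3" survive), lowercases, removes
#' stopwords and stems. Token order is preserved.
#'
#' @param text Character vector; elements are concatenated with spaces.
#' @param config An [analyzer_config()].
#' @return Character vector of analyzed tokens (possibly empty).
#' @export
analyze <- function(text, config = analyzer_config()) {
  stopifnot(inherits(config, "analyzer_config"))
  if (length(text) == 0) return(character(0))
  text <- paste(text, collapse = " ")
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  if (config$lowercase) text <- tolower(text)
  tokens <- strsplit(text, "[^a-z0-9]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!(tokens %in% config$stopwords)]
  if (length(tokens) && config$stemmer == "porter") {
    tokens <- porter_stem(tokens)
  }
  tokens
}

# Memoization cache for stems; keyed by raw token. Tokens repeat massively
# across a collection so this dominates indexing throughput.
.stem_cache <- new.env(parent = emptyenv())

#' Porter stemming
#'
#' An implementation of the original Porter (1980) suffix-stripping
#' algorithm for English, e.g. `"proteins"` → `"protein"`,
#' `"chemotaxis"` → `"chemotaxi"`, `"structure"` → `"structur"`.
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of stems, same length and order.
#' @export
porter_stem <- function(words) {
  out <- character(length(words))
  for (i in seq_along(words)) {
    w <- words[[i]]
    cached <- .stem_cache[[w]]
    if (is.null(cached)) {
      cached <- porter_stem_word(w)
      assign(w, cached, envir = .stem_cache)
    }
    out[[i]] <- cached
  }
  out
}

# --- Porter internals ------------------------------------------------------
# A word is represented as a character vector of single letters. A letter is
# a consonant if it is not a,e,i,o,u and not a 'y' preceded by a consonant.

porter_is_cons <- function(ltrs, i) {
  ch <- ltrs[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1) return(TRUE)
    return(!porter_is_cons(ltrs, i - 1))
  }
  TRUE
}

# measure m of the stem: number of VC sequences in [C](VC)^m[V]
porter_measure <- function(ltrs) {
  if (!length(ltrs)) return(0L)
  types <- vapply(seq_along(ltrs), function(i) porter_is_cons(ltrs, i), logical(1))
  runs <- rle(types)$values
  # count V followed by C transitions
  m <- 0L
  for (i in seq_along(runs)) {
    if (!runs[i] && i < length(runs) && runs[i + 1]) m <- m + 1L
  }
  m
}

porter_has_vowel <- function(ltrs) {
  if (!length(ltrs)) return(FALSE)
  any(!vapply(seq_along(ltrs), function(i) porter_is_cons(ltrs, i), logical(1)))
}

porter_double_cons <- function(ltrs) {
  n <- length(ltrs)
  n >= 2 && ltrs[n] == ltrs[n - 1] && porter_is_cons(ltrs, n)
}

# *o: stem ends consonant-vowel-consonant where the final consonant is not w,x,y
porter_cvc <- function(ltrs) {
  n <- length(ltrs)
  if (n < 3) return(FALSE)
  porter_is_cons(ltrs, n) && !porter_is_cons(ltrs, n - 1) &&
    porter_is_cons(ltrs, n - 2) && !(ltrs[n] %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  nchar(word) > nchar(suffix) &&
    substring(word, nchar(word) - nchar(suffix) + 1) == suffix
}

porter_stem_part <- function(word, suffix) {
  substring(word, 1, nchar(word) - nchar(suffix))
}

porter_m_of <- function(word) porter_measure(strsplit(word, "")[[1]])

porter_stem_word <- function(word) {
  if (nchar(word) <= 2) return(word)

  # Step 1a
  if (porter_ends(word, "sses")) {
    word <- paste0(porter_stem_part(word, "sses"), "ss")
  } else if (porter_ends(word, "ies")) {
    word <- paste0(porter_stem_part(word, "ies"), "i")
  } else if (porter_ends(word, "ss")) {
    # unchanged
  } else if (porter_ends(word, "s")) {
    word <- porter_stem_part(word, "s")
  }

  # Step 1b
  fired <- FALSE
  if (porter_ends(word, "eed")) {
    stem <- porter_stem_part(word, "eed")
    if (porter_m_of(stem) > 0) word <- paste0(stem, "ee")
  } else if (porter_ends(word, "ed")) {
    stem <- porter_stem_part(word, "ed")
    if (porter_has_vowel(strsplit(stem, "")[[1]])) {
      word <- stem
      fired <- TRUE
    }
  } else if (porter_ends(word, "ing")) {
    stem <- porter_stem_part(word, "ing")
    if (porter_has_vowel(strsplit(stem, "")[[1]])) {
      word <- stem
      fired <- TRUE
    }
  }
  if (fired) {
    ltrs <- strsplit(word, "")[[1]]
    if (porter_ends(word, "at") || porter_ends(word, "bl") || porter_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (porter_double_cons(ltrs) && !(ltrs[length(ltrs)] %in% c("l", "s", "z"))) {
      word <- substring(word, 1, nchar(word) - 1)
    } else if (porter_m_of(word) == 1 && porter_cvc(ltrs)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c
  if (porter_ends(word, "y")) {
    stem <- porter_stem_part(word, "y")
    if (porter_has_vowel(strsplit(stem, "")[[1]])) word <- paste0(stem, "i")
  }

  # Step 2: longest matching suffix only
  step2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
             izer = "ize", abli = "able", alli = "al", entli = "ent",
             eli = "e", ousli = "ous", ization = "ize", ation = "ate",
             ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
             ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  word <- porter_apply_rules(word, step2, min_m = 1)

  # Step 3
  step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  word <- porter_apply_rules(word, step3, min_m = 1)

  # Step 4
  step4 <- c(al = "", ance = "", ence = "", er = "", ic = "", able = "",
             ible = "", ant = "", ement = "", ment = "", ent = "",
             ion = "", ou = "", ism = "", ate = "", iti = "", ous = "",
             ive = "", ize = "")
  sufs <- names(step4)
  sufs <- sufs[order(-nchar(sufs))]
  for (s in sufs) {
    if (porter_ends(word, s)) {
      stem <- porter_stem_part(word, s)
      ok <- porter_m_of(stem) > 1
      if (ok && s == "ion") {
        last <- substring(stem, nchar(stem))
        ok <- last %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (porter_ends(word, "e")) {
    stem <- porter_stem_part(word, "e")
    m <- porter_m_of(stem)
    if (m > 1 || (m == 1 && !porter_cvc(strsplit(stem, "")[[1]]))) {
      word <- stem
    }
  }
  # Step 5b
  ltrs <- strsplit(word, "")[[1]]
  if (porter_m_of(word) > 1 && porter_double_cons(ltrs) && ltrs[length(ltrs)] == "l") {
    word <- substring(word, 1, nchar(word) - 1)
  }
  word
}

# Apply the longest matching suffix rule of a rule table; at most one rule
# fires (Porter semantics: the longest-suffix match decides, and if its m
# condition fails nothing else is tried).
porter_apply_rules <- function(word, rules, min_m) {
  sufs <- names(rules)
  sufs <- sufs[order(-nchar(sufs))]
  for (s in sufs) {
    if (porter_ends(word, s)) {
      stem <- porter_stem_part(word, s)
      if (porter_m_of(stem) > min_m - 1) {
        word <- paste0(stem, rules[[s]])
      }
      return(word)
    }
  }
  word
}
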