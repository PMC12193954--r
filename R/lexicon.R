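#' Load a PD term dictionary
#'
#' Reads a dictionary file with one term per line, an optional tab-separated
#' tag (`exercise`, `medication`, `symptom`, `advocacy`, `other`) and `#`
#' comments. Terms are lowercased, deduplicated and stemmed token-by-token;
#' multi-word terms are preserved and later matched as consecutive token
#' sequences.
#'
#' @param path path to a UTF-8 dictionary file.
#' @return an object of class `term_dictionary`: list with `terms` (character),
#'   `stems` (character, parallel to `terms`), `tags` (named character).
#' @export
load_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("dictionary file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- tolower(vapply(parts, `[`, character(1), 1L))
  terms <- trimws(terms)
  tags <- vapply(parts, function(p) if (length(p) > 1L) trimws(tolower(p[2L])) else "other",
                 character(1))
  if (anyDuplicated(terms)) {
    message("collapsing ", sum(duplicated(terms)), " duplicate dictionary term(s)")
    keep <- !duplicated(terms)
    terms <- terms[keep]
    tags <- tags[keep]
  }
  stems <- vapply(strsplit(terms, "[ ]+"), function(tok) {
    paste(porter_stem(gsub("[^a-z0-9]", "", tok)), collapse = " ")
  }, character(1))
  structure(list(terms = terms, stems = stems, tags = stats::setNames(tags, terms)),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("PD term dictionary:", length(x$terms), "terms\n")
  tab <- table(x$tags)
  cat(paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' The bundled starter dictionary
#'
#' A reconstructed PD term dictionary (symptom, medication, advocacy and
#' exercise vocabulary) shipped for tests and worked examples. It is a
#' synthetic stand-in for a full clinical dictionary, not a published
#' resource.
#'
#' @return a `term_dictionary`.
#' @export
default_dictionary <- function() {
  load_dictionary(system.file("extdata", "pd_terms_synthetic.tsv",
                              package = "pdposts", mustWork = TRUE))
}

# n-gram join helper: consecutive k-token sequences as strings
token_ngrams <- function(tokens, k) {
  n <- length(tokens)
  if (n < k) return(character(0))
  if (k == 1L) return(tokens)
  idx <- seq_len(n - k + 1L)
  out <- tokens[idx]
  for (j in seq_len(k - 1L)) out <- paste(out, tokens[idx + j])
  out
}

#' Flag a post against the dictionary
#'
#' A post is flagged if any dictionary term matches either its unstemmed or
#' its stemmed token sequence; multi-word terms must appear as consecutive
#' tokens (after stopword removal).
#'
#' @param text a single raw post text, or the output element of
#'   [preprocess_for_match()].
#' @param dict a `term_dictionary`.
#' @return list with `hit` (logical) and `matched_terms` (character vector of
#'   dictionary terms, with their tags as names).
#' @export
dictionary_flag <- function(text, dict) {
  pp <- if (is.character(text)) preprocess_for_match(text)[[1L]] else text
  term_tok <- strsplit(dict$terms, " ", fixed = TRUE)
  sizes <- lengths(term_tok)
  matched <- logical(length(dict$terms))
  for (k in sort(unique(sizes))) {
    sel <- sizes == k
    grams_un <- token_ngrams(pp$unstemmed, k)
    grams_st <- token_ngrams(pp$stemmed, k)
    matched[sel] <- (dict$terms[sel] %in% grams_un) | (dict$stems[sel] %in% grams_st)
  }
  terms <- dict$terms[matched]
  list(hit = any(matched),
       matched_terms = stats::setNames(terms, NULL),
       tags = unname(dict$tags[terms]))
}

#' Flag a corpus against the dictionary
#'
#' Vectorized form of [dictionary_flag()].
#'
#' @param texts character vector of raw post texts.
#' @param dict a `term_dictionary`.
#' @return data.frame with `hit`, `n_terms`, list-columns `matched_terms` and
#'   `tags`.
#' @export
dictionary_flag_corpus <- function(texts, dict) {
  pp <- preprocess_for_match(texts)
  res <- lapply(pp, dictionary_flag, dict = dict)
  data.frame(
    hit = vapply(res, `[[`, logical(1), "hit"),
    n_terms = vapply(res, function(r) length(r$matched_terms), integer(1)),
    matched_terms = I(lapply(res, `[[`, "matched_terms")),
    tags = I(lapply(res, `[[`, "tags"))
  )
}

#' Explicit-mention rules
#'
#' Rule-based flags applied to the raw (un-preprocessed) text: a
#' case-insensitive substring match for "parkinson", and a case-sensitive
#' word-boundary match for the standalone abbreviation "PD" (so "updated"
#' never matches).
#'
#' @param text character vector of raw texts.
#' @return data.frame with logical columns `parkinson` and `pd_abbrev`.
#' @export
explicit_mention <- function(text) {
  data.frame(
    parkinson = grepl("parkinson", text, ignore.case = TRUE),
    pd_abbrev = grepl("\\bPD\\b", text, perl = TRUE)
  )
}
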