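# Keys whose character values count as author text when found under a
# timestamped record.
TEXT_KEYS <- c("post", "comment", "description", "title")

# Recursively walk parsed JSON. A record that carries a numeric "timestamp"
# yields one entry per text-bearing key in its subtree; nested timestamped
# records are handled independently.
harvest_node <- function(node, acc) {
  if (!is.list(node)) return(acc)
  nms <- names(node)
  has_ts <- !is.null(nms) && "timestamp" %in% nms &&
    is.numeric(node$timestamp) && length(node$timestamp) == 1L
  if (has_ts) {
    texts <- collect_texts(node)
    for (k in seq_along(texts$text)) {
      acc[[length(acc) + 1L]] <- list(timestamp = as.numeric(node$timestamp),
                                      text = texts$text[k], key = texts$key[k])
    }
    return(acc)
  }
  for (child in node) acc <- harvest_node(child, acc)
  acc
}

# Gather text-key values below a timestamped record, stopping at nested
# timestamped records.
collect_texts <- function(node) {
  text <- character(0); key <- character(0)
  walk <- function(x, top) {
    if (!is.list(x)) return(invisible())
    nms <- names(x)
    if (!top && !is.null(nms) && "timestamp" %in% nms) return(invisible())
    if (!is.null(nms)) {
      for (nm in intersect(nms, TEXT_KEYS)) {
        v <- x[[nm]]
        if (is.character(v) && length(v) == 1L && nzchar(trimws(v))) {
          text <<- c(text, v); key <<- c(key, nm)
        }
      }
    }
    for (child in x) walk(child, FALSE)
  }
  walk(node, TRUE)
  list(text = text, key = key)
}

#' Read a participant's export archive
#'
#' Walks every JSON file under `dir`, collecting (timestamp, text) pairs from
#' the text-bearing keys `post`, `comment`, `description` and `title`.
#' Records without a timestamp or without text are skipped; malformed files
#' are recorded as errors without aborting the harvest.
#'
#' @param dir archive directory of one participant.
#' @param participant_id id attached to each entry (defaults to the directory
#'   name).
#' @return data.frame of raw entries (`participant_id`, `timestamp`, `text`,
#'   `source_file`, `kind`) with a `errors` attribute (named character vector
#'   of per-file error messages; empty when all files parsed).
#' @export
read_export <- function(dir, participant_id = basename(normalizePath(dir))) {
  files <- list.files(dir, pattern = "\\.json$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no JSON files under ", dir)
  entries <- list()
  errors <- character(0)
  for (f in files) {
    parsed <- tryCatch(jsonlite::fromJSON(f, simplifyVector = FALSE),
                       error = function(e) e)
    if (inherits(parsed, "error")) {
      errors[basename(f)] <- conditionMessage(parsed)
      next
    }
    acc <- harvest_node(parsed, list())
    if (length(acc)) {
      entries[[f]] <- data.frame(
        timestamp = vapply(acc, `[[`, numeric(1), "timestamp"),
        text = vapply(acc, `[[`, character(1), "text"),
        key = vapply(acc, `[[`, character(1), "key"),
        source_file = basename(f), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(entries)) do.call(rbind, entries) else
    data.frame(timestamp = numeric(0), text = character(0),
               key = character(0), source_file = character(0),
               stringsAsFactors = FALSE)
  kind_map <- c(post = "post", comment = "comment", description = "caption",
                title = "other")
  out <- data.frame(participant_id = rep(participant_id, nrow(out)),
                    timestamp = out$timestamp, text = out$text,
                    source_file = out$source_file,
                    kind = unname(kind_map[out$key]),
                    stringsAsFactors = FALSE)
  out <- out[out$timestamp >= 0 & nzchar(trimws(out$text)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

# Characters that betray UTF-8 text mis-read as Latin-1.
MOJIBAKE_MARKERS <- "[ÂÃâ€]"

# Windows-1252 specials: Unicode codepoint -> byte. Together with the
# identity mapping for codepoints <= 0xFF this inverts the "sloppy CP1252"
# decoding real exports exhibit (control bytes 0x80-0x9F appear either as
# CP1252 punctuation or as C1 controls).
CP1252_SPECIALS <- c(
  `8364` = 0x80, `8218` = 0x82, `402` = 0x83, `8222` = 0x84, `8230` = 0x85,
  `8224` = 0x86, `8225` = 0x87, `710` = 0x88, `8240` = 0x89, `352` = 0x8A,
  `8249` = 0x8B, `338` = 0x8C, `381` = 0x8E, `8216` = 0x91, `8217` = 0x92,
  `8220` = 0x93, `8221` = 0x94, `8226` = 0x95, `8211` = 0x96, `8212` = 0x97,
  `732` = 0x98, `8482` = 0x99, `353` = 0x9A, `8250` = 0x9B, `339` = 0x9C,
  `382` = 0x9E, `376` = 0x9F)

# Map a mis-decoded string back to its underlying bytes; NULL when some
# character cannot have come from a single-byte decoding.
sloppy1252_bytes <- function(s) {
  cp <- utf8ToInt(s)
  out <- integer(length(cp))
  small <- cp <= 0xFF
  out[small] <- cp[small]
  if (any(!small)) {
    mapped <- CP1252_SPECIALS[as.character(cp[!small])]
    if (anyNA(mapped)) return(NULL)
    out[!small] <- as.integer(mapped)
  }
  as.raw(out)
}

#' Repair text encoding
#'
#' Best-effort repair of UTF-8-read-as-Latin-1 mojibake ("cafÃ©"
#' becomes "café"), followed by Unicode NFC normalization. A string is
#' only rewritten when it contains mojibake marker characters and its
#' Latin-1-byte reinterpretation is valid UTF-8, which makes the function
#' idempotent; anything unrepairable passes through unchanged.
#'
#' @param text character vector.
#' @return repaired character vector.
#' @export
normalize_encoding <- function(text) {
  out <- enc2utf8(text)
  for (pass in 1:3) {  # double-encoded text needs repeated unwinding
    cand <- grepl(MOJIBAKE_MARKERS, out)
    if (!any(cand)) break
    fixed <- vapply(out[cand], function(s) {
      raw <- sloppy1252_bytes(s)
      if (is.null(raw)) return(s)
      y <- rawToChar(raw)
      Encoding(y) <- "UTF-8"
      if (!validUTF8(y)) return(s)
      y
    }, character(1), USE.NAMES = FALSE)
    if (identical(fixed, out[cand])) break
    out[cand] <- fixed
  }
  stringi::stri_trans_nfc(out)
}

NUMBER_WORDS <- c("one", "two", "three", "four", "five", "six", "seven",
                  "eight", "nine", "ten", "eleven", "twelve")

#' Strip relative-time memory phrases
#'
#' Removes in-text shared-memory timestamps of the form quantity (digits or a
#' number word) + time unit (day/month/year) + "ago", together with
#' punctuation attached to the phrase; surrounding text is preserved and
#' whitespace re-collapsed. Phrases without a quantity ("years ago") are left
#' alone.
#'
#' @param text character vector.
#' @return character vector with memory phrases removed.
#' @export
strip_memory_timestamps <- function(text) {
  qty <- paste0("(\\d+|", paste(NUMBER_WORDS, collapse = "|"), ")")
  pat <- paste0("(?i)[[:punct:]]*\\s*\\b", qty,
                "\\s+(year|years|month|months|day|days)\\s+ago\\b\\s*[-:.,!]*\\s*")
  out <- gsub(pat, " ", text, perl = TRUE)
  squash_ws(out)
}

#' Deduplicate raw entries into posts
#'
#' Applies the two-stage rule within one participant's entries: (1) entries
#' with identical timestamp and (whitespace-normalized, case-sensitive) text
#' collapse to one; (2) for entries sharing the same text, processed in time
#' order, the earliest is retained and a later occurrence is kept only when
#' at least 180 s have elapsed since the most recently *retained* occurrence
#' of that text (intentional reshares survive, rapid re-exports do not).
#'
#' @param entries data.frame with at least `participant_id`, `timestamp`,
#'   `text`, `kind` (one participant).
#' @param window near-duplicate window in seconds (default 180).
#' @return data.frame of posts (`participant_id`, `post_id`, `timestamp`,
#'   `kind`, `text`), time-sorted.
#' @export
deduplicate <- function(entries, window = 180) {
  if (!nrow(entries)) {
    return(data.frame(participant_id = character(0), post_id = character(0),
                      timestamp = numeric(0), kind = character(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  if (length(unique(entries$participant_id)) > 1L)
    stop("deduplicate() operates on a single participant")
  norm <- squash_ws(entries$text)
  ord <- order(entries$timestamp)
  e <- entries[ord, , drop = FALSE]
  norm <- norm[ord]
  # stage 1: exact duplicates (timestamp + text)
  keep1 <- !duplicated(paste(format(e$timestamp, scientific = FALSE), norm,
                             sep = "\r"))
  e <- e[keep1, , drop = FALSE]
  norm <- norm[keep1]
  # stage 2: near duplicates within text groups, anchored to last retained
  keep2 <- logical(nrow(e))
  for (idx in split(seq_len(nrow(e)), norm)) {
    last_kept <- -Inf
    for (i in idx) {
      if (e$timestamp[i] - last_kept >= window || is.infinite(last_kept)) {
        keep2[i] <- TRUE
        last_kept <- e$timestamp[i]
      }
    }
  }
  out <- e[keep2, , drop = FALSE]
  norm <- norm[keep2]
  data.frame(participant_id = out$participant_id,
             post_id = post_id(out$participant_id, out$timestamp, norm),
             timestamp = out$timestamp, kind = out$kind, text = norm,
             stringsAsFactors = FALSE)
}

#' Ingest one archive into a clean post stream
#'
#' Convenience wrapper: harvest, repair encoding, strip memory phrases,
#' deduplicate.
#'
#' @inheritParams read_export
#' @return deduplicated post data.frame (see [deduplicate()]).
#' @export
ingest_archive <- function(dir, participant_id = basename(normalizePath(dir))) {
  raw <- read_export(dir, participant_id)
  raw$text <- strip_memory_timestamps(normalize_encoding(raw$text))
  raw <- raw[nzchar(raw$text), , drop = FALSE]
  out <- deduplicate(raw)
  attr(out, "errors") <- attr(raw, "errors")
  out
}

#' Write / read a clean corpus as TSV
#'
#' Tab and newline characters inside texts are escaped so the file stays one
#' row per post.
#'
#' @param corpus post data.frame.
#' @param path file path.
#' @return `path` (write) or the corpus (read).
#' @export
write_corpus_tsv <- function(corpus, path) {
  out <- corpus
  out$text <- gsub("\t", "\\\\t", gsub("\n", "\\\\n", out$text))
  out$timestamp_iso <- format(as.POSIXct(out$timestamp, origin = "1970-01-01",
                                         tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  write.table(out[, c("participant_id", "post_id", "timestamp_iso", "kind", "text")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_corpus_tsv
#' @export
read_corpus_tsv <- function(path) {
  x <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  x$text <- gsub("\\\\n", "\n", gsub("\\\\t", "\t", x$text))
  x$timestamp <- as.numeric(as.POSIXct(x$timestamp_iso, format = "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC"))
  x
}
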