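#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict glm binomial pnorm pt rnorm runif rbinom sd
#'   setNames quantile rlnorm
#' @importFrom utils head tail combn write.table read.delim
NULL

# Collapse internal whitespace and trim. Used both for dedup text equality and
# for the stable post id, so the two can never disagree.
squash_ws <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Stable post identifier
#'
#' Hashes participant id, timestamp and whitespace-normalized text into a
#' short stable id. The same (participant, timestamp, text) triple always maps
#' to the same id, so ground-truth labels written by the synthetic generator
#' can be joined back to posts recovered from archives after encoding repair
#' and memory-timestamp stripping.
#'
#' @param participant_id character vector.
#' @param timestamp numeric epoch seconds (UTC).
#' @param text character vector; whitespace is collapsed before hashing.
#' @return character vector of hexadecimal ids.
#' @export
post_id <- function(participant_id, timestamp, text) {
  key <- paste(participant_id, format(timestamp, scientific = FALSE, trim = TRUE),
               squash_ws(text), sep = "\r")
  vapply(key, function(k) digest::digest(k, algo = "xxhash64", serialize = FALSE),
         character(1), USE.NAMES = FALSE)
}

# ISO date helper: accepts Date, "YYYY-MM-DD", "YYYY" (coerced to July 1, with
# a message, since diagnosis recall is often year-granular), NA or "".
parse_flex_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  blank <- is.na(x) | !nzchar(trimws(x))
  ymd <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  yonly <- grepl("^\\d{4}$", x)
  out[ymd] <- as.Date(x[ymd])
  if (any(yonly & !blank)) {
    message("coercing ", sum(yonly & !blank), " year-only date(s) to July 1")
    out[yonly] <- as.Date(paste0(x[yonly], "-07-01"))
  }
  out
}

ts_to_date <- function(ts) {
  as.Date(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
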