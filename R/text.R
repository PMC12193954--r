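# Fixed English stopword list, bundled so that preprocessing is reproducible
# across installations (no external resource is consulted). Deliberately
# conservative: function words only, no content words.
PD_STOPWORDS <- c(
  "a", "about", "above", "after", "again", "against", "all", "am", "an", "and",
  "any", "are", "aren", "as", "at", "be", "because", "been", "before", "being",
  "below", "between", "both", "but", "by", "can", "cannot", "could", "did",
  "do", "does", "doing", "don", "down", "during", "each", "few", "for", "from",
  "further", "had", "has", "have", "having", "he", "her", "here", "hers",
  "herself", "him", "himself", "his", "how", "i", "if", "in", "into", "is",
  "isn", "it", "its", "itself", "just", "me", "more", "most", "my", "myself",
  "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or", "other",
  "our", "ours", "ourselves", "out", "over", "own", "same", "she", "should",
  "so", "some", "such", "than", "that", "the", "their", "theirs", "them",
  "themselves", "then", "there", "these", "they", "this", "those", "through",
  "to", "too", "under", "until", "up", "very", "was", "we", "were", "what",
  "when", "where", "which", "while", "who", "whom", "why", "will", "with",
  "you", "your", "yours", "yourself", "yourselves")

#' The bundled stopword list
#' @return character vector of lowercase stopwords.
#' @export
pd_stopwords <- function() PD_STOPWORDS

# Irregular English noun plurals for the noun-default lemmatizer.
NOUN_EXCEPTIONS <- c(
  feet = "foot", teeth = "tooth", geese = "goose", mice = "mouse",
  lice = "louse", men = "man", women = "woman", children = "child",
  oxen = "ox", people = "person", knives = "knife", wives = "wife",
  lives = "life", leaves = "leaf", halves = "half", selves = "self",
  shelves = "shelf", wolves = "wolf", loaves = "loaf", scarves = "scarf",
  calves = "calf", elves = "elf", thieves = "thief", dice = "die",
  analyses = "analysis", diagnoses = "diagnosis", crises = "crisis",
  theses = "thesis", criteria = "criterion", phenomena = "phenomenon")

# Words whose trailing "s" is not a plural marker; never stripped.
NOUN_S_KEEP <- c(
  "always", "perhaps", "news", "yes", "his", "this", "thanks", "diabetes",
  "species", "series", "scissors", "glasses", "pants", "is", "was", "has",
  "less", "plus", "bus", "gas", "class", "grass", "stress", "press",
  "process", "progress", "address", "business", "illness", "fitness",
  "dizziness", "stiffness", "weakness", "darkness", "sadness", "tiredness",
  "parkinsons", "pilates")

#' Noun-default lemmatization
#'
#' Reduces regular and irregular English noun plurals to their singular
#' (dictionary) form, treating every token as a noun: verb inflections such as
#' gerunds are deliberately left untouched ("trembling" stays "trembling").
#' Unknown or uninflected tokens pass through unchanged.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of lemmas, same length.
#' @export
lemmatize <- function(tokens) {
  if (!length(tokens)) return(character(0))
  out <- tokens
  exc <- NOUN_EXCEPTIONS[tokens]
  hit <- !is.na(exc)
  out[hit] <- exc[hit]
  todo <- !hit & !(tokens %in% NOUN_S_KEEP) & nchar(tokens) > 3L &
    endsWith(tokens, "s")
  w <- out[todo]
  w <- ifelse(grepl("ies$", w) & nchar(w) > 4L, sub("ies$", "y", w),
       ifelse(grepl("(ss|us|is)es$", w), sub("es$", "", w),
       ifelse(grepl("(x|z|ch|sh)es$", w), sub("es$", "", w),
       ifelse(grepl("ss$|us$|is$", w), w,
       sub("s$", "", w)))))
  out[todo] <- w
  out
}

# Tokenize a cleaned lowercase string on whitespace; drop empties.
ws_tokenize <- function(x) {
  toks <- strsplit(x, " ", fixed = TRUE)
  lapply(toks, function(t) t[nzchar(t)])
}

#' Preprocess text for dictionary matching
#'
#' Lowercases, removes punctuation, tokenizes on whitespace, drops stopwords
#' and stems each token, mirroring the matching pipeline used for the term
#' dictionary. Apostrophes are removed rather than split, so "Parkinson's"
#' becomes the single token "parkinsons".
#'
#' @param text character vector of raw post texts.
#' @return a list with one element per input text, each a list with
#'   `unstemmed` and `stemmed` token vectors (stopwords removed from both).
#' @export
preprocess_for_match <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9 ]+", " ", gsub("['’]", "", x))
  toks <- ws_tokenize(x)
  lapply(toks, function(t) {
    t <- t[!(t %in% PD_STOPWORDS)]
    list(unstemmed = t, stemmed = porter_stem(t))
  })
}

#' Clean text for the classifier feature pipeline
#'
#' Removes URLs, @-tags and #-hashtags (the whole token in each case), strips
#' punctuation and special characters, collapses whitespace, lowercases and
#' drops stopwords. Duplicated tokens are kept: term frequency carries signal.
#'
#' @param text character vector.
#' @return list of token vectors, one per input text.
#' @export
clean_for_model <- function(text) {
  x <- gsub("(https?://|www\\.)\\S+", " ", text, perl = TRUE)
  x <- gsub("(^|\\s)[@#]\\S+", " ", x, perl = TRUE)
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", gsub("['’]", "", x))
  toks <- ws_tokenize(squash_ws(x))
  lapply(toks, function(t) t[!(t %in% PD_STOPWORDS)])
}
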