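# Porter suffix-stripping stemmer (the 1980 algorithm), implemented directly
# because dictionary matching and every downstream lexicon test depend on one
# fixed, reproducible stemmer. Both dictionary terms and post tokens go through
# this same function, so matching is internally consistent by construction.

porter_is_cons <- function(w, i) {
  ch <- w[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(w, i - 1L))
  }
  TRUE
}

# measure m of the stem w[1..j]: number of VC sequences
porter_m <- function(w, j) {
  if (j < 1L) return(0L)
  types <- vapply(seq_len(j), function(i) porter_is_cons(w, i), logical(1))
  # collapse runs
  runs <- rle(types)$values
  # strip leading consonant run and trailing vowel run, count VC pairs
  if (length(runs) && runs[1]) runs <- runs[-1]
  if (length(runs) && !runs[length(runs)]) runs <- runs[-length(runs)]
  length(runs) %/% 2L
}

porter_has_vowel <- function(w, j) {
  if (j < 1L) return(FALSE)
  any(!vapply(seq_len(j), function(i) porter_is_cons(w, i), logical(1)))
}

porter_double_cons <- function(w, j) {
  j >= 2L && w[j] == w[j - 1L] && porter_is_cons(w, j)
}

# *o: stem ends cvc, second c not w, x or y
porter_cvc <- function(w, j) {
  if (j < 3L) return(FALSE)
  porter_is_cons(w, j - 2L) && !porter_is_cons(w, j - 1L) && porter_is_cons(w, j) &&
    !(w[j] %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  n <- nchar(word)
  s <- nchar(suffix)
  n > s && substring(word, n - s + 1L, n) == suffix
}

porter1 <- function(word) {
  if (nchar(word) <= 2L) return(word)
  chars <- function() strsplit(word, "", fixed = TRUE)[[1]]
  stem_len <- function(suffix) nchar(word) - nchar(suffix)
  m_for <- function(suffix) porter_m(chars(), stem_len(suffix))
  vowel_for <- function(suffix) porter_has_vowel(chars(), stem_len(suffix))
  repl <- function(suffix, with) {
    word <<- paste0(substring(word, 1L, stem_len(suffix)), with)
  }

  # Step 1a
  if (porter_ends(word, "sses")) repl("sses", "ss")
  else if (porter_ends(word, "ies")) repl("ies", "i")
  else if (porter_ends(word, "ss")) NULL
  else if (porter_ends(word, "s")) repl("s", "")

  # Step 1b
  flag1b <- FALSE
  if (porter_ends(word, "eed")) {
    if (m_for("eed") > 0L) repl("eed", "ee")
  } else if (porter_ends(word, "ed") && vowel_for("ed")) {
    repl("ed", ""); flag1b <- TRUE
  } else if (porter_ends(word, "ing") && vowel_for("ing")) {
    repl("ing", ""); flag1b <- TRUE
  }
  if (flag1b) {
    if (porter_ends(word, "at")) repl("at", "ate")
    else if (porter_ends(word, "bl")) repl("bl", "ble")
    else if (porter_ends(word, "iz")) repl("iz", "ize")
    else {
      w <- chars(); j <- length(w)
      if (porter_double_cons(w, j) && !(w[j] %in% c("l", "s", "z"))) {
        word <- substring(word, 1L, j - 1L)
      } else if (porter_m(w, j) == 1L && porter_cvc(w, j)) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c
  if (porter_ends(word, "y") && vowel_for("y")) repl("y", "i")

  step_rules <- function(rules, mmin) {
    for (k in seq_len(nrow(rules))) {
      suf <- rules[k, 1L]
      if (porter_ends(word, suf)) {
        if (m_for(suf) > mmin) repl(suf, rules[k, 2L])
        return(invisible())  # longest match attempted once per step
      }
    }
  }

  # Step 2 (rules ordered so longer suffixes are tried first within a final letter)
  step2 <- rbind(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
    c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
    c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
    c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
    c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble"),
    c("logi", "log"))
  # longest-first ordering matters: sort by suffix length, descending
  step2 <- step2[order(-nchar(step2[, 1L])), , drop = FALSE]
  step_rules(step2, 0L)

  step3 <- rbind(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", ""))
  step3 <- step3[order(-nchar(step3[, 1L])), , drop = FALSE]
  step_rules(step3, 0L)

  # Step 4: m > 1, delete
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
             "ic", "ou")
  step4 <- step4[order(-nchar(step4))]
  for (suf in step4) {
    if (porter_ends(word, suf)) {
      if (suf == "ion") {
        pre <- substring(word, stem_len("ion"), stem_len("ion"))
        if (m_for("ion") > 1L && pre %in% c("s", "t")) repl("ion", "")
      } else if (m_for(suf) > 1L) repl(suf, "")
      break
    }
  }

  # Step 5a
  if (porter_ends(word, "e")) {
    m <- m_for("e")
    if (m > 1L) repl("e", "")
    else if (m == 1L) {
      w <- chars(); j <- length(w) - 1L
      if (!porter_cvc(w, j)) repl("e", "")
    }
  }
  # Step 5b
  w <- chars(); j <- length(w)
  if (porter_m(w, j) > 1L && porter_double_cons(w, j) && w[j] == "l") {
    word <- substring(word, 1L, j - 1L)
  }
  word
}

#' Porter stem of each token
#'
#' Suffix-stripping stemmer used for dictionary matching (e.g. "trembling"
#' becomes "trembl"). Results are cached per unique token, so stemming a long
#' corpus costs one pass over its vocabulary.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems, same length as `tokens`.
#' @export
porter_stem <- function(tokens) {
  if (!length(tokens)) return(character(0))
  u <- unique(tokens)
  stems <- vapply(u, porter1, character(1), USE.NAMES = FALSE)
  stems[match(tokens, u)]
}
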