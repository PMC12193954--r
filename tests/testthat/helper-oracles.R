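# Independent reference implementations used as oracles. Deliberately written
# in a different shape from the package code (explicit O(n^2) scans, pairwise
# counts) so agreement is informative.

# Brute-force deduplication: stage 1 drops identical (timestamp, text) pairs;
# stage 2 walks entries in time order and, for each, scans ALL previously
# retained entries for the latest retained occurrence of the same text.
brute_dedup <- function(ts, text, window = 180) {
  ord <- order(ts)
  ts <- ts[ord]; text <- text[ord]
  seen_exact <- character(0)
  keep <- logical(length(ts))
  ret_ts <- numeric(0); ret_text <- character(0)
  for (i in seq_along(ts)) {
    key <- paste(ts[i], text[i], sep = "\r")
    if (key %in% seen_exact) next
    seen_exact <- c(seen_exact, key)
    same <- which(ret_text == text[i])
    if (!length(same) || ts[i] - max(ret_ts[same]) >= window) {
      keep[i] <- TRUE
      ret_ts <- c(ret_ts, ts[i]); ret_text <- c(ret_text, text[i])
    }
  }
  data.frame(timestamp = ts[keep], text = text[keep], stringsAsFactors = FALSE)
}

# AUC as the concordant-pair fraction (ties count one half).
brute_auc <- function(y, prob) {
  pos <- prob[y == 1]; neg <- prob[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Small fast labeled corpus + participants for classifier unit tests.
tiny_labeled <- function(n = 400, seed = 5) {
  synth_labeled_corpus(n = n, seed = seed)
}

# A linearly separable toy problem in the package's sparse format.
separable_toy <- function(n = 60, seed = 3) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- Matrix::sparseMatrix(
    i = seq_len(n), j = y + 1L, x = 1, dims = c(n, 3))
  x[, 3] <- runif(n)  # noise column
  colnames(x) <- c("neg", "pos", "noise")
  list(x = methods::as(x, "CsparseMatrix"), y = y)
}
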