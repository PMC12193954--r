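#' Load a token-to-cluster lookup table
#'
#' Two-column TSV (token, cluster id). Any resource with this shape can be
#' supplied; the package bundles a small synthetic table covering common
#' social-media vocabulary for tests and examples.
#'
#' @param path TSV path; default: the bundled synthetic table.
#' @return named character vector token -> cluster id.
#' @export
load_cluster_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "word_clusters_synthetic.tsv",
                        package = "pdposts", mustWork = TRUE)
  }
  x <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(x) < 2L) stop("cluster table must have two columns: token, cluster id")
  stats::setNames(as.character(x[[2L]]), tolower(as.character(x[[1L]])))
}

#' Map tokens to cluster ids
#'
#' Out-of-vocabulary tokens map to the reserved id `"OOV"`.
#'
#' @param tokens character vector.
#' @param cluster_table named character vector from [load_cluster_table()].
#' @return character vector of cluster ids.
#' @export
map_clusters <- function(tokens, cluster_table) {
  if (is.null(cluster_table)) stop("cluster table is missing")
  if (!length(tokens)) return(character(0))
  out <- unname(cluster_table[tokens])
  out[is.na(out)] <- "OOV"
  out
}

# 1..3-gram lemma terms of one token vector
lemma_ngrams <- function(lemmas) {
  c(token_ngrams(lemmas, 1L), token_ngrams(lemmas, 2L), token_ngrams(lemmas, 3L))
}

# Age at posting from age at interview and the interview/post date gap.
age_at_posting <- function(posts, participants) {
  i <- match(posts$participant_id, participants$id)
  if (anyNA(i)) stop("posts reference unknown participants")
  age <- participants$age_at_interview[i]
  ivw <- parse_flex_date(participants$interview_date)[i]
  if (anyNA(age) || anyNA(ivw))
    stop("participants need age_at_interview and interview_date for features")
  pmax(age - as.numeric(ivw - ts_to_date(posts$timestamp)) / 365.25, 0)
}

# sparse doc x term count matrix for a list of term vectors, given a vocab
count_matrix <- function(doc_terms, vocab) {
  idx <- lapply(doc_terms, function(t) {
    i <- match(t, vocab)
    i[!is.na(i)]
  })
  lens <- lengths(idx)
  rows <- rep.int(seq_along(idx), lens)
  cols <- unlist(idx, use.names = FALSE)
  if (is.null(cols)) cols <- integer(0)
  # duplicated (row, col) pairs sum into counts
  Matrix::sparseMatrix(i = rows, j = cols, x = rep.int(1, length(cols)),
                       dims = c(length(doc_terms), length(vocab)))
}

# TF-IDF block: raw count x smoothed idf, rows L2-normalized
tfidf_block <- function(counts, idf) {
  m <- counts %*% Matrix::Diagonal(x = idf)
  nrm <- sqrt(Matrix::rowSums(m^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% m
}

#' Fit the model feature space on training data
#'
#' Builds, from training posts only: the lemma 1-3-gram vocabulary and the
#' cluster unigram vocabulary (both restricted to terms appearing in at least
#' two training posts) with smoothed IDF weights `ln((1+N)/(1+df)) + 1`;
#' min/max bounds for age at posting; and the categorical levels (gender,
#' diagnosis group) seen in training. Applying the fitted space to new posts
#' never changes it.
#'
#' @param train_posts data.frame with `participant_id`, `timestamp`, `text`.
#' @param train_participants participant table (id, gender, group,
#'   age_at_interview, interview_date).
#' @param cluster_table from [load_cluster_table()].
#' @return object of class `feature_space`.
#' @export
fit_feature_space <- function(train_posts, train_participants,
                              cluster_table = load_cluster_table()) {
  if (nrow(train_posts) < 2L) stop("need at least two training posts")
  toks <- clean_for_model(train_posts$text)
  lemmas <- lapply(toks, lemmatize)
  grams <- lapply(lemmas, lemma_ngrams)
  df_lemma <- table(unlist(lapply(grams, unique)))
  lemma_vocab <- sort(names(df_lemma)[df_lemma >= 2L])
  clusters <- lapply(toks, map_clusters, cluster_table = cluster_table)
  df_clust <- table(unlist(lapply(clusters, unique)))
  cluster_vocab <- sort(names(df_clust)[df_clust >= 2L])
  if (!length(lemma_vocab) && !length(cluster_vocab))
    stop("degenerate training set: no term survives the document-frequency threshold")
  N <- nrow(train_posts)
  idf <- function(vocab, df) log((1 + N) / (1 + as.numeric(df[vocab]))) + 1
  ages <- age_at_posting(train_posts, train_participants)
  i <- match(train_posts$participant_id, train_participants$id)
  structure(list(
    lemma_vocab = lemma_vocab, lemma_idf = idf(lemma_vocab, df_lemma),
    cluster_vocab = cluster_vocab, cluster_idf = idf(cluster_vocab, df_clust),
    cluster_table = cluster_table,
    age_bounds = range(ages),
    gender_levels = sort(unique(train_participants$gender[i])),
    group_levels = sort(unique(train_participants$group[i])),
    n_train = N), class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat("feature space:", length(x$lemma_vocab), "lemma n-grams,",
      length(x$cluster_vocab), "clusters,",
      length(x$gender_levels) + length(x$group_levels) + 1L,
      "demographic columns; fitted on", x$n_train, "posts\n")
  invisible(x)
}

one_hot <- function(values, levels, prefix) {
  m <- Matrix::sparseMatrix(
    i = which(values %in% levels),
    j = match(values[values %in% levels], levels),
    x = 1, dims = c(length(values), length(levels)))
  colnames(m) <- paste0(prefix, levels)
  m
}

#' Build the feature matrix under a fitted space
#'
#' Columns: lemma TF-IDF block, cluster TF-IDF block, min-max-scaled age at
#' posting (clipped to training bounds), one-hot gender and diagnosis-group
#' blocks (levels unseen in training give all-zero blocks). All entries are
#' nonnegative and finite.
#'
#' @param posts data.frame with `participant_id`, `timestamp`, `text`.
#' @param participants participant table.
#' @param space a fitted [fit_feature_space()] object.
#' @return sparse `dgCMatrix`, rows in post order.
#' @export
build_features <- function(posts, participants, space) {
  stopifnot(inherits(space, "feature_space"))
  toks <- clean_for_model(posts$text)
  lemmas <- lapply(toks, lemmatize)
  grams <- lapply(lemmas, lemma_ngrams)
  lem <- tfidf_block(count_matrix(grams, space$lemma_vocab), space$lemma_idf)
  colnames(lem) <- paste0("lemma:", space$lemma_vocab)
  clusters <- lapply(toks, map_clusters, cluster_table = space$cluster_table)
  clu <- tfidf_block(count_matrix(clusters, space$cluster_vocab), space$cluster_idf)
  colnames(clu) <- paste0("cluster:", space$cluster_vocab)
  ages <- age_at_posting(posts, participants)
  lo <- space$age_bounds[1]; hi <- space$age_bounds[2]
  age_scaled <- if (hi > lo) pmin(pmax((ages - lo) / (hi - lo), 0), 1)
                else rep(0, length(ages))
  i <- match(posts$participant_id, participants$id)
  gen <- one_hot(participants$gender[i], space$gender_levels, "gender:")
  grp <- one_hot(participants$group[i], space$group_levels, "group:")
  age_col <- Matrix::Matrix(age_scaled, ncol = 1, sparse = TRUE)
  colnames(age_col) <- "age_at_posting"
  out <- cbind(lem, clu, age_col, gen, grp)
  methods::as(out, "CsparseMatrix")
}
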