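#' Fit the PD-related post classifier
#'
#' End-to-end model fit in the classic modelling idiom: takes a labeled
#' corpus, performs the stratified 80/20 split, fits all feature
#' transformations on the training portion only (lemma 1-3-gram TF-IDF,
#' cluster TF-IDF, normalized age at posting, one-hot demographics), trains
#' the candidate families by stratified cross-validated grid search scoring
#' macro recall, adds the soft-voting ensemble, evaluates every model on the
#' held-out test set with bootstrap confidence intervals and ROC/AUC, and
#' selects the recall-optimal model.
#'
#' @param labeled data.frame with `participant_id`, `timestamp`, `text`,
#'   `label` (0/1).
#' @param participants participant table (id, group, gender,
#'   age_at_interview, interview_date).
#' @param families candidate families (default: all seven).
#' @param grids hyperparameter grids, see [default_grids()].
#' @param test_fraction held-out share (default 0.2).
#' @param B bootstrap resamples for test CIs.
#' @param seed integer seed governing split, folds, training and bootstrap.
#' @param cluster_table token-to-cluster lookup, see [load_cluster_table()].
#' @param with_ensemble include the soft-voting ensemble (default TRUE).
#' @return object of class `pd_classifier`: list with `space`, `candidates`,
#'   `reports`, `selected`, `split`, and the data sizes.
#' @export
fit_pd_classifier <- function(labeled, participants, families = FAMILIES,
                              grids = default_grids(), test_fraction = 0.2,
                              B = 1000, seed = 1,
                              cluster_table = load_cluster_table(),
                              with_ensemble = TRUE) {
  stopifnot(all(c("participant_id", "timestamp", "text", "label") %in% names(labeled)))
  y <- as.integer(labeled$label)
  sp <- split_data(y, test_fraction, seed = seed)
  train <- labeled[sp$train, , drop = FALSE]
  test <- labeled[sp$test, , drop = FALSE]
  space <- fit_feature_space(train, participants, cluster_table)
  x_train <- build_features(train, participants, space)
  x_test <- build_features(test, participants, space)
  candidates <- train_candidates(x_train, y[sp$train], families, grids,
                                 seed = seed)
  if (with_ensemble) candidates$ensemble <- build_ensemble(candidates[families])
  reports <- lapply(candidates, evaluate_model, x_test = x_test,
                    y_test = y[sp$test], B = B, seed = seed)
  selected <- select_model(reports)
  structure(list(space = space, candidates = candidates, reports = reports,
                 selected = selected, split = sp,
                 n_train = nrow(train), n_test = nrow(test),
                 prevalence = mean(y), seed = seed),
            class = "pd_classifier")
}

#' @export
print.pd_classifier <- function(x, ...) {
  cat("PD-related post classifier\n")
  cat(sprintf("  corpus: %d posts (%.1f%% PD-related), %d train / %d test\n",
              x$n_train + x$n_test, 100 * x$prevalence, x$n_train, x$n_test))
  r <- x$reports[[x$selected]]
  cat(sprintf("  selected: %s (test macro recall %.2f, AUC %.2f)\n",
              x$selected, r$macro_recall, r$auc))
  invisible(x)
}

#' Summarize all candidate models
#'
#' One row per model with test macro recall, precision and F1 (each with its
#' bootstrap CI), AUC and cross-validated recall, sorted by macro recall.
#'
#' @param object a `pd_classifier`.
#' @param ... unused.
#' @return data.frame.
#' @export
summary.pd_classifier <- function(object, ...) {
  rows <- lapply(names(object$reports), function(nm) {
    r <- object$reports[[nm]]
    data.frame(model = nm,
               recall = r$macro_recall,
               recall_lo = r$ci[1, "macro_recall"], recall_hi = r$ci[2, "macro_recall"],
               precision = r$macro_precision,
               precision_lo = r$ci[1, "macro_precision"], precision_hi = r$ci[2, "macro_precision"],
               f1 = r$macro_f1,
               f1_lo = r$ci[1, "macro_f1"], f1_hi = r$ci[2, "macro_f1"],
               auc = r$auc, cv_recall = r$cv_macro_recall,
               selected = nm == object$selected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$recall, -out$f1), , drop = FALSE]
}

#' Predict PD-relatedness probabilities for new posts
#'
#' @param object a `pd_classifier`.
#' @param posts data.frame with `participant_id`, `timestamp`, `text`.
#' @param participants participant table covering the posts' authors.
#' @param threshold classification threshold (boundary positive).
#' @param model which model to use (default: the selected one).
#' @param ... unused.
#' @return data.frame with `probability` and `label`.
#' @export
predict.pd_classifier <- function(object, posts, participants,
                                  threshold = 0.5, model = object$selected,
                                  ...) {
  x <- build_features(posts, participants, object$space)
  predict_posts(object$candidates[[model]], x, threshold)
}

#' ROC curve of a fitted classifier
#'
#' @param x a `pd_classifier`.
#' @param model which model's test ROC to draw (default: selected).
#' @param ... passed to [graphics::plot()].
#' @export
plot.pd_classifier <- function(x, model = x$selected, ...) {
  r <- x$reports[[model]]
  graphics::plot(r$roc$fpr, r$roc$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s (AUC = %.2f)", model, r$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
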