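#' Stratified train/test split
#'
#' Splits post indices into disjoint, exhaustive train/test sets, stratified
#' by label: each class contributes `round(n_class * test_fraction)` posts to
#' the test set. Deterministic given the seed.
#'
#' @param labels integer 0/1 vector.
#' @param test_fraction test share in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_data <- function(labels, test_fraction = 0.2, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least two examples per class")
  set.seed(seed)
  test <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_fraction)
    n_test <- min(max(n_test, 1L), length(idx) - 1L)
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

# stratified fold assignment: per class, shuffled round-robin, so per-class
# fold sizes differ by at most one
stratified_folds <- function(y, nfolds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  folds
}

# macro-averaged recall/precision/F1 from labels and predictions
macro_metrics <- function(y, pred) {
  classes <- c(0L, 1L)
  rec <- prec <- f1 <- numeric(2)
  for (k in 1:2) {
    cl <- classes[k]
    tp <- sum(y == cl & pred == cl)
    fn <- sum(y == cl & pred != cl)
    fp <- sum(y != cl & pred == cl)
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0   # no predictions of cl
    f1[k] <- if (prec[k] + rec[k] > 0 && !is.na(rec[k]))
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  c(macro_recall = mean(rec), macro_precision = mean(prec), macro_f1 = mean(f1))
}

# rank-based AUC (equals the trapezoid over all thresholds, midrank ties)
auc_score <- function(y, prob) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(y, prob) {
  ord <- order(prob, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1L)
  fp <- cumsum(y[ord] == 0L)
  keep <- !duplicated(prob[ord], fromLast = TRUE)  # one point per threshold
  rbind(data.frame(fpr = 0, tpr = 0, threshold = Inf),
        data.frame(fpr = fp[keep] / max(sum(y == 0L), 1),
                   tpr = tp[keep] / max(sum(y == 1L), 1),
                   threshold = prob[ord][keep]))
}

#' Train candidate families with stratified cross-validated grid search
#'
#' For each family, every grid row is scored by stratified `nfolds`-fold
#' cross-validated macro recall (labels predicted at threshold 0.5); the best
#' row (ties: first in the grid) is refit on the full training set.
#'
#' @param x training feature matrix (`dgCMatrix`).
#' @param y integer 0/1 labels.
#' @param families subset of the seven supported family names.
#' @param grids named list of data.frame grids; defaults to [default_grids()].
#' @param seed integer seed.
#' @param nfolds folds (default 5).
#' @return named list of fitted candidates, each with `cv_macro_recall`,
#'   `params` and the fitted model.
#' @export
train_candidates <- function(x, y, families = FAMILIES, grids = default_grids(),
                             seed = 1, nfolds = 5) {
  stopifnot(all(families %in% FAMILIES))
  set.seed(seed)
  folds <- stratified_folds(y, nfolds)
  for (f in seq_len(nfolds)) {
    if (length(unique(y[folds == f])) < 2L)
      stop("fold ", f, " contains a single class")
  }
  out <- list()
  for (family in families) {
    grid <- grids[[family]]
    if (is.null(grid)) grid <- default_grids()[[family]]
    scores <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      fold_rec <- numeric(nfolds)
      for (f in seq_len(nfolds)) {
        tr <- folds != f
        fit <- fit_candidate(family, x[tr, , drop = FALSE], y[tr], params)
        prob <- predict_prob(fit, x[!tr, , drop = FALSE])
        fold_rec[f] <- macro_metrics(y[!tr], as.integer(prob >= 0.5))["macro_recall"]
      }
      scores[g] <- mean(fold_rec)
    }
    best <- which.max(scores)   # ties: first grid row
    fit <- fit_candidate(family, x, y, as.list(grid[best, , drop = FALSE]))
    fit$cv_macro_recall <- scores[best]
    fit$cv_scores <- cbind(grid, cv_macro_recall = scores)
    out[[family]] <- fit
  }
  out
}

#' Soft-voting ensemble over fitted candidates
#'
#' Ensemble probability is the unweighted mean of member probabilities;
#' classification at 0.5 (boundary positive).
#'
#' @param candidates list of fitted candidates from [train_candidates()].
#' @return object of class `pd_candidate` with family `"ensemble"`.
#' @export
build_ensemble <- function(candidates) {
  if (!length(candidates)) stop("no candidates to combine")
  structure(list(family = "ensemble", params = list(),
                 fit = candidates,
                 cv_macro_recall = mean(vapply(candidates, `[[`, numeric(1),
                                               "cv_macro_recall"))),
            class = "pd_candidate")
}

# predict_prob dispatch for the ensemble family
predict_prob_ensemble <- function(object, x) {
  probs <- vapply(object$fit, predict_prob, numeric(nrow(x)), x = x)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

candidate_prob <- function(object, x) {
  if (object$family == "ensemble") predict_prob_ensemble(object, x)
  else predict_prob(object, x)
}

#' Predict with a fitted candidate
#'
#' @param model a fitted candidate (or ensemble).
#' @param x feature matrix in the fitted space.
#' @param threshold classification threshold; probability at the boundary is
#'   classified positive.
#' @return data.frame with `probability` and `label`.
#' @export
predict_posts <- function(model, x, threshold = 0.5) {
  prob <- candidate_prob(model, x)
  data.frame(probability = prob, label = as.integer(prob >= threshold))
}

#' Evaluate a model on a held-out test set
#'
#' Macro recall/precision/F1 with percentile bootstrap confidence intervals
#' (test-set resampling), ROC points and AUC.
#'
#' @param model fitted candidate or ensemble.
#' @param x_test,y_test held-out features and labels.
#' @param B bootstrap resamples (default 1000).
#' @param seed integer seed for resampling.
#' @param conf confidence level (default 0.95).
#' @return object of class `model_report`.
#' @export
evaluate_model <- function(model, x_test, y_test, B = 1000, seed = 1,
                           conf = 0.95) {
  if (length(unique(y_test)) < 2L) stop("test set contains a single class")
  prob <- candidate_prob(model, x_test)
  pred <- as.integer(prob >= 0.5)
  point <- macro_metrics(y_test, pred)
  set.seed(seed)
  n <- length(y_test)
  boot <- matrix(NA_real_, B, 3)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y_test[idx])) == 2L) break
    }
    boot[b, ] <- macro_metrics(y_test[idx], pred[idx])
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  colnames(ci) <- names(point)
  structure(list(
    family = model$family, params = model$params,
    cv_macro_recall = model$cv_macro_recall %||% NA_real_,
    macro_recall = unname(point["macro_recall"]),
    macro_precision = unname(point["macro_precision"]),
    macro_f1 = unname(point["macro_f1"]),
    ci = ci, auc = auc_score(y_test, prob),
    roc = roc_points(y_test, prob), n_test = n), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("%s: macro recall %.3f (%.3f-%.3f), precision %.3f, F1 %.3f, AUC %.3f (n=%d)\n",
              x$family, x$macro_recall, x$ci[1, "macro_recall"],
              x$ci[2, "macro_recall"], x$macro_precision, x$macro_f1,
              x$auc, x$n_test))
  invisible(x)
}

#' Select the recall-optimal model
#'
#' Returns the name of the report maximizing macro recall; ties are broken by
#' macro F1, then by the documented family order (the order of `reports`).
#'
#' @param reports named list of `model_report`s.
#' @return name of the selected report.
#' @export
select_model <- function(reports) {
  if (!length(reports)) stop("no reports")
  rec <- vapply(reports, `[[`, numeric(1), "macro_recall")
  f1 <- vapply(reports, `[[`, numeric(1), "macro_f1")
  best <- which(rec == max(rec))
  if (length(best) > 1L) best <- best[f1[best] == max(f1[best])]
  names(reports)[best[1L]]
}
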