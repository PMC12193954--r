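test_that("stratified split follows the per-class rounding rule and the seed", {
  labels <- c(rep(1L, 35), rep(0L, 65))
  sp <- split_data(labels, 0.2, seed = 4)
  expect_identical(length(sp$test), 20L)
  expect_identical(sum(labels[sp$test]), 7L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  sp2 <- split_data(labels, 0.2, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_data(labels, 0), "between 0 and 1")
  expect_error(split_data(c(0, 0, 1), 0.2), "two examples per class")
})

test_that("stratified folds preserve the class ratio within one example", {
  set.seed(5)
  y <- c(rep(1L, 237), rep(0L, 463))
  folds <- pdposts:::stratified_folds(y, 5)
  for (cl in 0:1) {
    sizes <- table(folds[y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("macro metrics equal hand computation on a fixed confusion matrix", {
  # TP=8 FN=2 TN=9 FP=1: recall_pos 0.8, recall_neg 0.9 -> macro 0.85
  y <- c(rep(1L, 10), rep(0L, 10))
  pred <- c(rep(1L, 8), rep(0L, 2), rep(0L, 9), 1L)
  m <- pdposts:::macro_metrics(y, pred)
  expect_equal(unname(m["macro_recall"]), 0.85)
  prec_pos <- 8 / 9; prec_neg <- 9 / 11
  expect_equal(unname(m["macro_precision"]), mean(c(prec_neg, prec_pos)))
  f1_pos <- 2 * prec_pos * 0.8 / (prec_pos + 0.8)
  f1_neg <- 2 * prec_neg * 0.9 / (prec_neg + 0.9)
  expect_equal(unname(m["macro_f1"]), mean(c(f1_neg, f1_pos)))
})

test_that("AUC equals the brute-force concordant-pair fraction", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    prob <- round(runif(n), 2)   # rounding forces ties
    expect_equal(pdposts:::auc_score(y, prob), brute_auc(y, prob))
  }
  expect_equal(pdposts:::auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
})

test_that("every family separates a linearly separable toy problem", {
  toy <- separable_toy()
  cands <- train_candidates(toy$x, toy$y, grids = default_grids(), seed = 2,
                            nfolds = 5)
  for (nm in names(cands)) {
    expect_gte(cands[[nm]]$cv_macro_recall, 0.99)
  }
})

test_that("permuted labels give chance-level cross-validated recall", {
  lc <- tiny_labeled(n = 240, seed = 6)
  space <- fit_feature_space(lc$posts, lc$participants)
  x <- build_features(lc$posts, lc$participants, space)
  set.seed(11)
  recalls <- replicate(10, {
    y_perm <- sample(lc$posts$label)
    cands <- train_candidates(x, y_perm, families = c("naive-bayes", "decision-tree"),
                              seed = sample.int(1000, 1))
    mean(vapply(cands, `[[`, numeric(1), "cv_macro_recall"))
  })
  expect_lt(abs(mean(recalls) - 0.5), 0.1)
})

test_that("grid search is deterministic under a fixed seed", {
  toy <- separable_toy(n = 80, seed = 9)
  c1 <- train_candidates(toy$x, toy$y, families = c("naive-bayes", "gradient-boosted-trees"),
                         seed = 21)
  c2 <- train_candidates(toy$x, toy$y, families = c("naive-bayes", "gradient-boosted-trees"),
                         seed = 21)
  expect_identical(c1[["naive-bayes"]]$params, c2[["naive-bayes"]]$params)
  expect_equal(c1[["naive-bayes"]]$cv_scores, c2[["naive-bayes"]]$cv_scores)
})

test_that("the ensemble averages member probabilities", {
  toy <- separable_toy(n = 40, seed = 12)
  cands <- train_candidates(toy$x, toy$y, families = c("naive-bayes", "decision-tree",
                                                       "gradient-boosted-trees"),
                            seed = 3)
  ens <- build_ensemble(cands)
  probs <- vapply(cands, function(cand) pdposts:::predict_prob(cand, toy$x),
                  numeric(nrow(toy$x)))
  expect_equal(pdposts:::candidate_prob(ens, toy$x), unname(rowMeans(probs)))
  # all members identical -> ensemble behaves like the member
  ens1 <- build_ensemble(cands["naive-bayes"])
  expect_equal(pdposts:::candidate_prob(ens1, toy$x),
               pdposts:::predict_prob(cands[["naive-bayes"]], toy$x))
})

test_that("prediction threshold classifies the boundary as positive", {
  fake <- structure(list(family = "naive-bayes",
                         fit = list(log_prior = log(c(0.5, 0.5)),
                                    log_theta0 = log(c(0.5, 0.5)),
                                    log_theta1 = log(c(0.5, 0.5)))),
                    class = "pd_candidate")
  x <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 2))
  out <- predict_posts(fake, methods::as(x, "CsparseMatrix"))
  expect_equal(out$probability, 0.5)
  expect_identical(out$label, 1L)      # boundary rule
  expect_identical(predict_posts(fake, methods::as(x, "CsparseMatrix"),
                                 threshold = 0.51)$label, 0L)
})

test_that("model selection maximizes recall with F1 and order tie-breaks", {
  rep_stub <- function(recall, f1) list(macro_recall = recall, macro_f1 = f1)
  expect_identical(select_model(list(A = rep_stub(0.86, 0.8), B = rep_stub(0.84, 0.9))), "A")
  expect_identical(select_model(list(A = rep_stub(0.85, 0.8), B = rep_stub(0.85, 0.9))), "B")
  expect_identical(select_model(list(A = rep_stub(0.85, 0.9), B = rep_stub(0.85, 0.9))), "A")
  expect_identical(select_model(list(only = rep_stub(0.5, 0.5))), "only")
})

test_that("bootstrap CI brackets the point estimate and narrows with n", {
  # a fixed imperfect predictor: one presence stump, so the predicted label
  # is just the indicator column and the error rate is under direct control
  stump <- structure(list(family = "adaptive-boosting",
                          fit = list(feats = 1L, pols = 1L, alphas = 3)),
                     class = "pd_candidate")
  mk_case <- function(n, err = 0.25, seed) {
    set.seed(seed)
    y <- rbinom(n, 1, 0.4)
    pred <- ifelse(runif(n) < err, 1L - y, y)
    x <- Matrix::sparseMatrix(i = which(pred == 1L),
                              j = rep(1, sum(pred == 1L)),
                              x = 1, dims = c(n, 1))
    list(x = methods::as(x, "CsparseMatrix"), y = y)
  }
  width <- function(r) r$ci[2, "macro_recall"] - r$ci[1, "macro_recall"]
  big <- mk_case(800, seed = 31)
  rep_big <- evaluate_model(stump, big$x, big$y, B = 400, seed = 2)
  expect_lte(rep_big$ci[1, "macro_recall"], rep_big$macro_recall)
  expect_gte(rep_big$ci[2, "macro_recall"], rep_big$macro_recall)
  small_widths <- vapply(1:5, function(s) {
    sm <- mk_case(60, seed = 100 + s)
    width(evaluate_model(stump, sm$x, sm$y, B = 400, seed = 2))
  }, numeric(1))
  expect_lt(width(rep_big), mean(small_widths))
  expect_error(evaluate_model(stump, big$x[1:3, , drop = FALSE], c(1L, 1L, 1L)),
               "single class")
})
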