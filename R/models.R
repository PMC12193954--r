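# Candidate classifier families behind one internal interface:
# fit_candidate(family, x, y, params) -> fit; predict_prob(fit, x) -> P(y=1).
# x is a sparse dgCMatrix of nonnegative features, y an integer 0/1 vector.
# Established engines are used where available (e1071, ranger, rpart,
# xgboost); multinomial naive Bayes, k-NN probabilities and boosted stumps
# are implemented here on the sparse representation.

# Candidate families, in the documented tie-break order (simplest first):
# when two models tie on macro recall and macro F1, the earlier family wins.
FAMILIES <- c("naive-bayes", "decision-tree", "nearest-neighbor",
              "max-margin", "random-forest", "adaptive-boosting",
              "gradient-boosted-trees")

#' Default hyperparameter grids
#'
#' Small documented defaults per family; every value can be overridden by
#' passing a named list of data.frames to the training functions.
#'
#' @return named list of data.frame grids.
#' @export
default_grids <- function() {
  list(
    "nearest-neighbor" = data.frame(k = c(3, 5, 11)),
    "max-margin" = data.frame(cost = c(0.1, 1, 10)),
    "random-forest" = data.frame(num_trees = 100, min_node = c(1, 10)),
    "adaptive-boosting" = data.frame(rounds = c(25, 50)),
    "naive-bayes" = data.frame(alpha = c(0.1, 0.5, 1.0)),
    "decision-tree" = data.frame(maxdepth = c(4, 8, 30)),
    "gradient-boosted-trees" = data.frame(max_depth = c(3, 6), nrounds = 60)
  )
}

fit_candidate <- function(family, x, y, params) {
  fit <- switch(family,
    "naive-bayes" = fit_mnb(x, y, params$alpha),
    "nearest-neighbor" = list(x = x, y = y, k = params$k),
    "max-margin" = fit_svm_platt(x, y, params$cost),
    "random-forest" = fit_ranger(x, y, params$num_trees, params$min_node),
    "adaptive-boosting" = fit_ada_stumps(x, y, params$rounds),
    "decision-tree" = fit_rpart(x, y, params$maxdepth),
    "gradient-boosted-trees" = fit_xgb(x, y, params$max_depth, params$nrounds),
    stop("unknown family: ", family))
  structure(list(family = family, params = params, fit = fit),
            class = "pd_candidate")
}

predict_prob <- function(object, x) {
  f <- object$fit
  switch(object$family,
    "naive-bayes" = predict_mnb(f, x),
    "nearest-neighbor" = predict_knn(f, x),
    "max-margin" = predict_svm_platt(f, x),
    "random-forest" = {
      p <- predict(f, data.frame(as.matrix(x), check.names = FALSE),
                   num.threads = 1)$predictions
      if ("1" %in% colnames(p)) unname(p[, "1"]) else rep(0, nrow(x))
    },
    "adaptive-boosting" = predict_ada_stumps(f, x),
    "decision-tree" = {
      d <- as.data.frame(as.matrix(x))
      colnames(d) <- paste0("f", seq_len(ncol(d)))
      p <- predict(f, d, type = "prob")
      if ("1" %in% colnames(p)) unname(p[, "1"]) else rep(0, nrow(x))
    },
    "gradient-boosted-trees" = {
      predict(f, xgboost::xgb.DMatrix(x, nthread = 1))
    },
    stop("unknown family"))
}

# ---- multinomial naive Bayes -------------------------------------------------

fit_mnb <- function(x, y, alpha) {
  p <- ncol(x)
  s1 <- Matrix::colSums(x[y == 1L, , drop = FALSE])
  s0 <- Matrix::colSums(x[y == 0L, , drop = FALSE])
  list(log_prior = log(c(mean(y == 0L), mean(y == 1L))),
       log_theta0 = log((s0 + alpha) / (sum(s0) + alpha * p)),
       log_theta1 = log((s1 + alpha) / (sum(s1) + alpha * p)))
}

predict_mnb <- function(f, x) {
  l0 <- as.vector(x %*% f$log_theta0) + f$log_prior[1]
  l1 <- as.vector(x %*% f$log_theta1) + f$log_prior[2]
  1 / (1 + exp(l0 - l1))
}

# ---- k nearest neighbors -----------------------------------------------------

predict_knn <- function(f, x) {
  cross <- as.matrix(x %*% Matrix::t(f$x))
  d2 <- outer(Matrix::rowSums(x^2), rep(1, nrow(f$x))) +
    outer(rep(1, nrow(x)), Matrix::rowSums(f$x^2)) - 2 * cross
  k <- min(f$k, nrow(f$x))
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]   # distance ties broken by training index
    mean(f$y[nn])
  })
}

# ---- linear SVM with Platt-scaled probabilities ------------------------------

fit_svm_platt <- function(x, y, cost) {
  xd <- as.matrix(x)
  m <- e1071::svm(xd, factor(y, levels = c(0, 1)), kernel = "linear",
                  cost = cost, scale = FALSE)
  dv <- attr(predict(m, xd, decision.values = TRUE), "decision.values")[, 1]
  cal <- suppressWarnings(glm(y ~ dv, family = binomial()))
  list(svm = m, cal = cal)
}

predict_svm_platt <- function(f, x) {
  dv <- attr(predict(f$svm, as.matrix(x), decision.values = TRUE),
             "decision.values")[, 1]
  unname(predict(f$cal, data.frame(dv = dv), type = "response"))
}

# ---- random forest (ranger) --------------------------------------------------

fit_ranger <- function(x, y, num_trees, min_node) {
  d <- data.frame(as.matrix(x), check.names = FALSE)
  ranger::ranger(y = factor(y, levels = c(0, 1)), x = d,
                 num.trees = num_trees, min.node.size = min_node,
                 probability = TRUE, num.threads = 1,
                 seed = sample.int(.Machine$integer.max, 1))
}

# ---- AdaBoost on feature-presence decision stumps ----------------------------
# Each weak learner tests x[, j] > 0 with a polarity; weighted errors for all
# features are computed with two sparse matrix-vector products per round.

fit_ada_stumps <- function(x, y, rounds) {
  n <- nrow(x)
  b <- x
  b@x <- rep(1, length(b@x))     # presence indicator, same sparsity pattern
  bt <- Matrix::t(b)
  w <- rep(1 / n, n)
  ys <- 2 * y - 1
  feats <- integer(rounds); pols <- integer(rounds); alphas <- numeric(rounds)
  for (m in seq_len(rounds)) {
    w1 <- as.vector(bt %*% (w * (y == 0L)))          # err contribution, x>0 wrongly called 1
    w2 <- as.vector(bt %*% (w * (y == 1L)))
    wy <- sum(w * (y == 1L))
    err_pos <- w1 + (wy - w2)     # predict 1 when present
    err_neg <- 1 - err_pos        # flipped polarity
    jp <- which.min(err_pos); jn <- which.min(err_neg)
    if (err_pos[jp] <= err_neg[jn]) { j <- jp; pol <- 1L; err <- err_pos[jp] }
    else { j <- jn; pol <- -1L; err <- err_neg[jn] }
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    h <- ifelse(as.vector(x[, j] > 0), pol, -pol)
    w <- w * exp(-alpha * ys * h)
    w <- w / sum(w)
    feats[m] <- j; pols[m] <- pol; alphas[m] <- alpha
    if (err < 1e-09) { feats <- feats[1:m]; pols <- pols[1:m]; alphas <- alphas[1:m]; break }
  }
  list(feats = feats, pols = pols, alphas = alphas)
}

predict_ada_stumps <- function(f, x) {
  score <- numeric(nrow(x))
  for (m in seq_along(f$feats)) {
    h <- ifelse(as.vector(x[, f$feats[m]] > 0), f$pols[m], -f$pols[m])
    score <- score + f$alphas[m] * h
  }
  1 / (1 + exp(-2 * score))
}

# ---- CART (rpart) ------------------------------------------------------------

fit_rpart <- function(x, y, maxdepth) {
  d <- as.data.frame(as.matrix(x))
  colnames(d) <- paste0("f", seq_len(ncol(d)))
  d$.y <- factor(y, levels = c(0, 1))
  rpart::rpart(.y ~ ., data = d, method = "class",
               control = rpart::rpart.control(maxdepth = min(maxdepth, 30),
                                              cp = 0.001, xval = 0))
}

# ---- gradient-boosted trees (xgboost) ----------------------------------------

fit_xgb <- function(x, y, max_depth, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = max_depth, eta = 0.3,
                                   nthread = 1),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}
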