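test_that("Welch t from summary stats matches raw-data t.test", {
  set.seed(8)
  for (rep in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    want <- t.test(x, y)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(want$parameter), tolerance = 1e-10)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
  }
})

test_that("Welch edge cases: identical groups and the equal-n equal-sd limit", {
  z <- welch_t(5, 2, 10, 5, 2, 10)
  expect_equal(z$statistic, 0)
  expect_equal(z$effect_size, 0)
  expect_equal(z$df, 18)               # 2n - 2 in the balanced limit
  expect_error(welch_t(1, 0, 5, 2, 0, 5), "zero variance")
  expect_error(welch_t(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("Fisher exact matches the enumeration oracle on a table sweep", {
  tabs <- list(matrix(c(0, 10, 10, 0), 2), matrix(c(5, 5, 5, 5), 2),
               matrix(c(3, 1, 2, 7), 2), matrix(c(0, 0, 4, 6), 2),
               matrix(c(1, 2, 3, 4), 2), matrix(c(8, 2, 1, 9), 2))
  set.seed(13)
  for (k in 1:40) tabs[[length(tabs) + 1]] <- matrix(rpois(4, 4), 2)
  for (tab in tabs) {
    if (sum(tab) == 0) next
    got <- fisher_exact(tab)$p_value
    want <- stats::fisher.test(tab)$p.value
    expect_equal(got, want, tolerance = 1e-09, info = paste(tab, collapse = ","))
  }
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(0.5, 1, 1, 1), 2)), "integers")
})

test_that("signed-rank W uses the min-sum convention and drops zero pairs", {
  r <- wilcoxon_signed_rank(c(1, 1, 2), c(2, 3, 5))
  expect_equal(r$statistic, 0)   # all differences positive
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "usable")
  r2 <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(1, 5, 1, 9))
  expect_equal(r2$n_used, 3)     # one zero difference dropped
})

test_that("signed-rank p matches wilcox.test exactly on tie-free pairs", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:11, 1)
    pre <- rnorm(n); post <- rnorm(n)
    got <- wilcoxon_signed_rank(pre, post)
    want <- stats::wilcox.test(post, pre, paired = TRUE, exact = TRUE)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-09)
  }
})

test_that("signed-rank normal approximation is close to exact enumeration", {
  # tie-free pairs at n = 10..12: the normal approximation deviates from the
  # sign-flip enumeration by < 0.05 over the entire statistic support
  set.seed(19)
  for (n in 10:12) {
    for (rep in 1:10) {
      pre <- rnorm(n); post <- rnorm(n)
      exact <- wilcoxon_signed_rank(pre, post, exact_max = 12)
      approx <- wilcoxon_signed_rank(pre, post, exact_max = 0)
      expect_equal(exact$statistic, approx$statistic)
      expect_lt(abs(exact$p_value - approx$p_value), 0.05)
    }
  }
})

test_that("signed-rank is symmetric under negating all differences", {
  set.seed(23)
  pre <- rnorm(15); post <- rnorm(15)
  a <- wilcoxon_signed_rank(pre, post)
  b <- wilcoxon_signed_rank(post, pre)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("Mann-Whitney matches enumeration and wilcox.test on small samples", {
  expect_equal(mann_whitney_u(1:3, 4:6)$statistic, 0)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  r <- mann_whitney_u(x, y)
  expect_equal(r$statistic, length(x)^2 / 2)
  expect_gt(r$p_value, 0.9)
  set.seed(29)
  for (rep in 1:25) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    xx <- rnorm(nx); yy <- rnorm(ny)
    got <- mann_whitney_u(xx, yy)
    want <- stats::wilcox.test(xx, yy, exact = TRUE)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-09)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("two-sample tests are invariant to group order", {
  set.seed(31)
  x <- rnorm(12); y <- rnorm(20, 1)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  w1 <- welch_t(1, 2, 10, 3, 1, 15); w2 <- welch_t(3, 1, 15, 1, 2, 10)
  expect_equal(abs(w1$statistic), abs(w2$statistic))
  expect_equal(w1$p_value, w2$p_value)
})

test_that("Shapiro-Wilk wrapper detects skew and handles degenerate inputs", {
  set.seed(37)
  expect_lt(shapiro_wilk(rexp(100))$p_value, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
  # type-I calibration at n = 50 over 400 null draws
  rej <- mean(replicate(400, shapiro_wilk(rnorm(50))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("Cohen's kappa matches hand computation and edge conventions", {
  expect_equal(cohens_kappa(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  # both-yes 4, both-no 4, one disagreement each way: po 0.8, pe 0.5
  a <- c(rep(1, 5), rep(0, 5)); b <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(cohens_kappa(a, b), 0.6)
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)  # pe = 1 convention
  set.seed(41)
  k <- cohens_kappa(rbinom(4000, 1, 0.5), rbinom(4000, 1, 0.5))
  expect_lt(abs(k), 0.06)  # independent raters: kappa near 0
})

test_that("all battery p-values stay within [0, 1]", {
  set.seed(43)
  for (rep in 1:30) {
    p1 <- wilcoxon_signed_rank(rnorm(6), rnorm(6))$p_value
    p2 <- mann_whitney_u(rnorm(4), rnorm(5))$p_value
    p3 <- fisher_exact(matrix(rpois(4, 3), 2))$p_value
    expect_true(all(c(p1, p2, p3) >= 0 & c(p1, p2, p3) <= 1))
  }
})
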