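# Statistical battery. Conventions are fixed and documented: all p-values are
# two-sided; W is the smaller of the signed-rank sums and U the smaller of
# the two U statistics (the convention consistent with the printed
# statistic/p pairs this pipeline reproduces); zero differences are dropped
# before ranking; exact enumeration replaces the normal approximation at
# small n.

stat_result <- function(test, statistic, df = NA_real_, p_value, effect_size = NA_real_,
                        n_used, notes = "") {
  structure(list(test = test, statistic = statistic, df = df, p_value = p_value,
                 effect_size = effect_size, n_used = n_used, notes = notes),
            class = "pd_stat")
}

#' @export
print.pd_stat <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4), sep = "")
  if (!is.na(x$df)) cat(", df = ", format(x$df, digits = 5), sep = "")
  cat(", p = ", format(x$p_value, digits = 3), sep = "")
  if (!is.na(x$effect_size)) cat(", d = ", format(x$effect_size, digits = 3), sep = "")
  cat(" (n = ", paste(x$n_used, collapse = "/"), ")", sep = "")
  if (nzchar(x$notes)) cat(" [", x$notes, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Welch's t-test from summary statistics, with Cohen's d
#'
#' Computes t, Welch-Satterthwaite degrees of freedom, the two-sided p-value
#' and pooled-SD Cohen's d from group means, SDs and sizes.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return a `pd_stat` with `statistic` (t), fractional `df`, `p_value` and
#'   `effect_size` (Cohen's d, pooled SD with n-1 weights).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be nonnegative")
  if (sd1 == 0 && sd2 == 0) stop("zero variance in both groups")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- if (sp > 0) (mean1 - mean2) / sp else 0
  stat_result("welch_t", t, df, p, d, c(n1, n2))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities not exceeding
#' the observed table's probability (margins fixed).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return a `pd_stat`; `statistic` is the observed table probability.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (n == 0) stop("empty table")
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-07)]))
  stat_result("fisher_exact", p_obs, NA_real_, p, n_used = n)
}

# midranks of |x|
midrank <- function(x) rank(x, ties.method = "average")

# exact two-sided p for the signed-rank min-sum statistic by sign-flip
# enumeration (handles midranks from ties)
wilcoxon_exact_p <- function(ranks, w_obs) {
  n <- length(ranks)
  total <- sum(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  tpos <- as.vector(signs %*% ranks)
  wmin <- pmin(tpos, total - tpos)
  mean(wmin <= w_obs + 1e-09)
}

#' Wilcoxon signed-rank test for paired percentages
#'
#' Pairs with missing values or zero difference are dropped (the
#' "valid, non-identical pairs" rule); absolute differences are ranked with
#' midranks; W is the smaller of the positive/negative rank sums. The
#' two-sided p-value comes from exhaustive sign-flip enumeration when the
#' number of usable pairs is at most `exact_max`, otherwise from the
#' tie-corrected normal approximation (no continuity correction).
#'
#' @param pre,post equal-length paired numeric vectors.
#' @param exact_max enumeration threshold (default 12).
#' @return a `pd_stat` with `statistic` = W.
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_max = 12) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  d <- post - pre
  keep <- !is.na(d) & d != 0
  dropped <- length(d) - sum(keep)
  d <- d[keep]
  n <- length(d)
  if (n < 1) stop("no usable pairs (all missing or identical)")
  r <- midrank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  if (n <= exact_max) {
    p <- wilcoxon_exact_p(r, W)
    note <- sprintf("exact sign-flip enumeration; %d pair(s) dropped", dropped)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) stop("degenerate rank variance")
    z <- (w_pos - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    note <- sprintf("normal approximation with tie correction; %d pair(s) dropped",
                    dropped)
  }
  stat_result("wilcoxon_signed_rank", W, NA_real_, p, n_used = n, notes = note)
}

# exact two-sided p for min-U by enumeration of all group assignments over
# the observed (mid)ranks
mann_whitney_exact_p <- function(r, nx, u_obs) {
  n <- length(r)
  total_x <- utils::combn(n, nx, FUN = function(idx) sum(r[idx]))
  ux <- total_x - nx * (nx + 1) / 2
  uy <- nx * (n - nx) - ux
  mean(pmin(ux, uy) <= u_obs + 1e-09)
}

#' Mann-Whitney U test
#'
#' U is the smaller of the two U statistics (midranks under ties). The
#' two-sided p-value comes from exhaustive enumeration of group assignments
#' when `nx * ny <= exact_max`, otherwise from the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max enumeration threshold on `nx * ny` (default 100).
#' @return a `pd_stat` with `statistic` = U.
#' @export
mann_whitney_u <- function(x, y, exact_max = 100) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty")
  r <- midrank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  U <- min(ux, uy)
  if (nx * ny <= exact_max) {
    p <- mann_whitney_exact_p(r, nx, U)
    note <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) stop("degenerate rank variance (all values tied)")
    z <- (U - mu + 0.5) / sqrt(sigma2)   # continuity-corrected toward the mean
    p <- min(1, 2 * pnorm(z))
    if (U >= mu) p <- 1
    note <- "normal approximation with tie correction and continuity correction"
  }
  stat_result("mann_whitney_u", U, NA_real_, p, n_used = c(nx, ny), notes = note)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard algorithm with the battery's result
#' container and explicit degenerate-input handling.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return a `pd_stat` with `statistic` = W.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1L) stop("constant sample: W undefined")
  sw <- stats::shapiro.test(x)
  stat_result("shapiro_wilk", unname(sw$statistic), NA_real_, sw$p.value,
              n_used = length(x))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement with marginal-product expected agreement. When
#' both raters are constant and identical (expected agreement 1), kappa is
#' defined as 1.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return kappa (numeric scalar).
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors must have equal length")
  if (!length(labels_a)) stop("empty label vectors")
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}
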