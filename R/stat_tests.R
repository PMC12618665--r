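#' Statistical test results
#'
#' All tests in the battery return a one-row tibble with a common shape:
#' `method` (tag), `statistic`, `p_value`, `effect` (Cohen's d, r, or NA),
#' `n_a`, `n_b`. This keeps the orchestrated report a plain stackable table.
#'
#' @param method Short method tag.
#' @param statistic Test statistic.
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param effect Effect size, or NA.
#' @param n_a,n_b Group sizes (n_b = NA for one-sample tests).
#' @return One-row tibble.
#' @export
test_result <- function(method, statistic, p_value, effect = NA_real_,
                        n_a, n_b = NA_integer_) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  tibble::tibble(
    method = method, statistic = as.numeric(statistic),
    p_value = as.numeric(p_value), effect = as.numeric(effect),
    n_a = as.integer(n_a), n_b = as.integer(n_b)
  )
}

#' Two-sample t-test with Cohen's d
#'
#' Classical two-sided independent-samples t-test with pooled variance, plus
#' Cohen's d computed as the mean difference over the pooled SD. Errors on
#' degenerate (zero pooled variance) input.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A [test_result()] with method `"independent_t"`, `effect` = d.
#' @export
independent_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stopf("independent_t needs n >= 2 per group")
  pooled_var <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var <= 0) stopf("independent_t: zero pooled variance, d undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  d <- (mean(a) - mean(b)) / sqrt(pooled_var)
  test_result("independent_t", unname(ht$statistic), ht$p.value, d,
              length(a), length(b))
}

#' Paired (one-sample) t-test on differences
#'
#' Two-sided t-test of the mean of paired differences against zero.
#'
#' @param diffs Numeric vector of differences, length >= 2, non-constant.
#' @return A [test_result()] with method `"paired_t"`, `effect` = mean diff /
#'   SD of diffs (Cohen's d for paired data).
#' @export
paired_t <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) stopf("paired_t needs n >= 2")
  if (stats::sd(diffs) == 0) stopf("paired_t: differences are constant")
  ht <- stats::t.test(diffs, mu = 0)
  test_result("paired_t", unname(ht$statistic), ht$p.value,
              mean(diffs) / stats::sd(diffs), length(diffs))
}

#' Wilcoxon signed-rank test, exact for small samples
#'
#' Two-sided paired Wilcoxon signed-rank test. Zero differences are dropped
#' (Wilcoxon's original procedure; set `zero_method = "pratt"` to rank zeros
#' and then discard them from the statistic instead). Ties among the
#' non-zero |differences| receive midranks. For `n <= exact_limit` non-zero
#' pairs the p-value comes from the exact sign-flip distribution of the
#' positive-rank sum (all 2^n sign patterns, computed by convolution);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Paired numeric vectors (equal length); `y` defaults to zeros,
#'   so `x` alone may carry the differences.
#' @param zero_method `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @param exact_limit Largest n for exact enumeration (default 25).
#' @return A [test_result()] with method `"wilcoxon"`; `statistic` is the
#'   positive-rank sum W+. If all differences are zero the statistic and p
#'   are NA (undefined), with n_a = 0.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, zero_method = c("wilcoxon", "pratt"),
                                 exact_limit = 25L) {
  zero_method <- match.arg(zero_method)
  x <- as.numeric(x)
  if (is.null(y)) y <- numeric(length(x))
  if (length(x) != length(y)) stopf("wilcoxon_signed_rank needs paired vectors of equal length")
  d <- x - as.numeric(y)
  nonzero <- d != 0
  if (!any(nonzero)) {
    return(test_result("wilcoxon", NA_real_, NA_real_, NA_real_, 0L))
  }
  if (zero_method == "wilcoxon") {
    dd <- d[nonzero]
    r <- rank(abs(dd))
  } else {
    # Pratt: rank |d| including zeros, then drop the zeros' ranks
    r_all <- rank(abs(d))
    dd <- d[nonzero]
    r <- r_all[nonzero]
  }
  n <- length(dd)
  w_pos <- sum(r[dd > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, w_pos)
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
    z <- (w_pos - mu)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  test_result("wilcoxon", w_pos, p, NA_real_, n)
}

# Exact two-sided p for the signed-rank statistic: distribution of the
# positive-rank sum over all 2^n sign patterns. Midranks are half-integers,
# so everything is doubled to work on an integer lattice; the convolution
# enumerates the full sign distribution exactly.
signed_rank_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)  # index i-1 = doubled rank sum
  dist[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(length(dist) - ri)])
    dist <- (dist + shifted) / 2
  }
  w2 <- round(2 * w_obs)
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[(w2 + 1L):length(dist)])
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test, exact for small samples
#'
#' Two-sided rank-sum test of two independent samples. The statistic is
#' \eqn{U = \#\{(i,j): a_i > b_j\} + \tfrac12 \#\{a_i = b_j\}}, i.e. U for
#' the first sample. For `n_a + n_b <= exact_limit` the p-value comes from
#' full enumeration of all assignments of the pooled midranks to the two
#' groups; otherwise a normal approximation with tie correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_limit Largest pooled n for exact enumeration (default 12).
#' @return A [test_result()] with method `"mannwhitney"`, statistic U.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stopf("mann_whitney_u needs non-empty groups")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n <= exact_limit) {
    combos <- utils::combn(n, n_a)
    u_all <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
    tol <- 1e-9
    p_le <- mean(u_all <= u_obs + tol)
    p_ge <- mean(u_all >= u_obs - tol)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n_a * n_b / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * (n + 1 - tie_term)
    z <- u_obs - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  test_result("mannwhitney", u_obs, p, NA_real_, n_a, n_b)
}

#' Pearson correlation with least-squares p-value
#'
#' Pearson's r between two vectors with the usual two-sided p from the
#' t-transform on n - 2 degrees of freedom (equivalent to testing the slope
#' of the least-squares line).
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return A [test_result()] with method `"pearson_ls"`; `statistic` and
#'   `effect` both carry r.
#' @export
pearson_ls <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("pearson_ls needs vectors of equal length")
  if (length(x) < 3) stopf("pearson_ls needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("pearson_ls: constant input")
  ht <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  test_result("pearson_ls", r, ht$p.value, r, length(x))
}
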