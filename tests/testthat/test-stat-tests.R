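# helper: build a vector with exact mean and SD
vec_with <- function(n, mean, sd) {
  z <- seq_len(n)
  z <- (z - mean(z)) / sd(z)
  mean + sd * z
}

test_that("independent t-test with pooled d on identical and summary-matched groups", {
  same <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$effect, 0)
  # groups reconstructed from rounded summary statistics: d from the pooled-SD
  # formula is (23.5 - 15.7) / sqrt((4.3^2 + 6.6^2)/2)
  a <- vec_with(10, 23.5, 4.3); b <- vec_with(10, 15.7, 6.6)
  res <- independent_t(a, b)
  expect_equal(res$effect, (23.5 - 15.7) / sqrt((4.3^2 + 6.6^2) / 2),
               tolerance = 1e-9)
  expect_equal(res$effect, 1.4005, tolerance = 1e-3)
  expect_error(independent_t(c(0, 0), c(1, 1)), "pooled variance")
  expect_error(independent_t(1, c(1, 2)), "n >= 2")
})

test_that("independent t matches the base implementation and flips under swap", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    res <- independent_t(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
    swapped <- independent_t(b, a)
    expect_equal(swapped$statistic, -res$statistic)
    expect_equal(swapped$p_value, res$p_value)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
  }
})

test_that("paired t-test on differences matches closed forms", {
  flat <- paired_t(c(1, -1))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # mean 2, sd 1, n 3: t = 2 / (1/sqrt(3)) = 2 sqrt(3)
  res <- paired_t(c(1, 2, 3))
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-9)
  expect_error(paired_t(c(2, 2, 2)), "constant")
})

test_that("signed-rank exact p-values match hand enumeration", {
  # diffs +1,+2,+3: W = 6, attained with prob 1/8 per tail
  res <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.25)
  # equal vectors: all differences zero, undefined
  und <- wilcoxon_signed_rank(c(1, 2), c(1, 2))
  expect_true(is.na(und$p_value))
  expect_equal(und$n_a, 0L)
  # tied |differences| +1,-1 with midranks: p = 1
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1)
})

test_that("signed-rank matches the brute-force sign enumeration for n <= 8", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    # mix of continuous and tied integer differences, some zeros
    d <- if (i %% 2) round(rnorm(n, 0.3, 1.5)) else rnorm(n, 0.3, 1.5)
    if (all(d == 0)) d[1] <- 1
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$p_value, wilcoxon_brute_p(d), tolerance = 1e-12,
                 info = paste(round(d, 3), collapse = ","))
  }
})

test_that("signed-rank agrees with the reference exact test when ties are absent", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    d <- rnorm(n)
    res <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("rank-sum exact p-values match hand enumeration", {
  # complete separation of 2 vs 2: one of six arrangements per tail
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)
  # identical multisets: p = 1 by symmetry
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # single pair, a above b
  expect_equal(mann_whitney_u(5, 1)$statistic, 1)
})

test_that("rank-sum matches the brute-force assignment enumeration for n <= 8", {
  set.seed(27)
  for (i in 1:60) {
    n_a <- sample(1:5, 1); n_b <- sample(1:5, 1)
    if (n_a + n_b < 3) n_b <- n_b + 2
    a <- if (i %% 2) sample(1:4, n_a, replace = TRUE) else rnorm(n_a)
    b <- if (i %% 2) sample(1:4, n_b, replace = TRUE) else rnorm(n_b, 0.5)
    res <- mann_whitney_u(a, b)
    expect_equal(res$p_value, mannwhitney_brute_p(a, b), tolerance = 1e-12,
                 info = sprintf("a=%s b=%s", paste(a, collapse = ","),
                                paste(b, collapse = ",")))
  }
})

test_that("rank-sum agrees with the reference exact test when ties are absent", {
  set.seed(37)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), 0.5)
    res <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("correlation test recovers exact and null relationships", {
  perf <- pearson_ls(c(1, 2, 3), c(2, 4, 6))
  expect_equal(perf$statistic, 1)
  expect_equal(pearson_ls(c(1, 2, 3), c(3, 2, 1))$statistic, -1)
  # mean r over all permutations of y at n = 4 is zero by symmetry
  x <- c(1, 2, 3, 4)
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1)
  )
  rs <- apply(perms, 1, function(p) pearson_ls(x, p)$statistic)
  expect_equal(mean(rs), 0, tolerance = 1e-12)
  # p from the t transform with n - 2 df
  set.seed(47)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  res <- pearson_ls(x, y)
  r <- res$statistic
  tstat <- r * sqrt(10 / (1 - r^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), df = 10), tolerance = 1e-12)
  expect_error(pearson_ls(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_ls(c(1, 2), c(1, 2)), "n >= 3")
})
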