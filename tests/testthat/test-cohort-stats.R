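test_that("categorical summaries use the grand-total denominator", {
  df <- data.frame(grp = c("a", "b", "b", "b"))
  s <- summarize_categorical(df, "grp", levels = c("a", "b"))
  expect_equal(s$n, c(1L, 3L))
  expect_equal(s$percent, c(25, 75))

  one <- summarize_categorical(data.frame(grp = rep("z", 9)), "grp")
  expect_equal(one$percent, 100)

  # percents sum to 100 (within rounding) for any composition
  set.seed(12)
  df <- data.frame(grp = sample(letters[1:4], 101, replace = TRUE))
  s <- summarize_categorical(df, "grp")
  expect_lt(abs(sum(round(s$percent, 1)) - 100), 0.2)
})

test_that("continuous summaries give sample mean and n-1 SD", {
  s <- summarize_continuous(data.frame(v = c(1, 2, 3)), "v")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(summarize_continuous(data.frame(v = rep(4, 5)), "v")$sd, 0)

  set.seed(8)
  x <- stats::rnorm(100)
  s <- summarize_continuous(data.frame(v = x), "v")
  # two-pass oracle
  expect_equal(s$mean, sum(x) / 100, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(sum((x - sum(x) / 100)^2) / 99), tolerance = 1e-12)

  expect_error(summarize_continuous(data.frame(v = 1), "v"), "insufficient")
})

test_that("chi-square vs Fisher selection follows the expected-count rule", {
  r <- categorical_sex_test(matrix(c(10, 10, 10, 10), 2))
  expect_identical(r$method, "chi_square")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  tab <- matrix(c(20, 10, 10, 20), 2)
  r <- categorical_sex_test(tab)
  # closed-form 2x2 oracle: n (ad - bc)^2 / (r1 r2 c1 c2)
  oracle <- 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  expect_equal(r$statistic, oracle, tolerance = 1e-12)
  expect_equal(round(r$statistic, 4), 6.6667)

  r <- categorical_sex_test(matrix(c(1, 2, 9, 8), 2))  # expecteds 1.5 < 5
  expect_identical(r$method, "fisher")
  expect_true(is.na(r$statistic))
  expect_true(r$p >= 0 && r$p <= 1)

  expect_error(categorical_sex_test(matrix(c(0, 0, 3, 4), 2)), "margin")

  # statistic invariant to transposition
  set.seed(3)
  tab <- matrix(rpois(6, 30), 2, 3)
  expect_equal(categorical_sex_test(tab)$statistic,
               categorical_sex_test(t(tab))$statistic, tolerance = 1e-12)
})

test_that("Mann-Whitney: exact enumeration small-sample behaviour", {
  r <- continuous_sex_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  # enumeration oracle: rank-sum distribution over all C(6,3) assignments
  combos <- utils::combn(6, 3)
  u_all <- apply(combos, 2, function(idx) sum(idx) - 6)
  p_oracle <- mean(u_all <= 0 | u_all >= 9)   # two-sided, U in {0..9}
  expect_equal(r$p, p_oracle)
  expect_equal(r$p, 0.1)

  expect_equal(continuous_sex_test(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(21)
  a <- stats::rnorm(200)
  b <- stats::rnorm(200, mean = 1)
  expect_lt(continuous_sex_test(a, b)$p, 0.001)

  expect_error(continuous_sex_test(numeric(0), 1:3), "non-empty")
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- 1:20
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  set.seed(17)
  a <- stats::rnorm(50)
  b <- 0.4 * a + stats::rnorm(50)
  r <- pearson_correlation(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$r, oracle, tolerance = 1e-12)
  t_stat <- oracle * sqrt(48 / (1 - oracle^2))
  expect_equal(r$p, 2 * stats::pt(-abs(t_stat), 48), tolerance = 1e-12)

  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
})

test_that("ICC(2,1) equals 1 on identity, ~0 on noise, and matches aov oracle", {
  x <- c(3.2, 4.1, 5.0, 2.2, 7.7)
  expect_equal(test_retest_icc(x, x)$icc, 1)

  set.seed(13)
  a <- stats::rnorm(500)
  b <- stats::rnorm(500)
  expect_lt(abs(test_retest_icc(a, b)$icc), 0.1)

  # hand-built 5x2 table against mean squares from stats::aov
  m1 <- c(9, 8, 7, 10, 6)
  m2 <- c(8.5, 8.2, 6.4, 9.1, 6.6)
  res <- test_retest_icc(m1, m2)
  long <- data.frame(y = c(m1, m2),
                     subj = factor(rep(1:5, 2)),
                     rater = factor(rep(1:2, each = 5)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 / 5 * (msc - mse))
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_lte(res$icc, 1)
})

test_that("table builders are permutation-invariant over subject order", {
  set.seed(29)
  df <- data.frame(grp = sample(c("p", "q", "r"), 60, replace = TRUE),
                   v = stats::rnorm(60))
  perm <- df[sample(60), ]
  expect_equal(summarize_categorical(df, "grp", levels = c("p", "q", "r")),
               summarize_categorical(perm, "grp", levels = c("p", "q", "r")))
  expect_equal(summarize_continuous(df, "v"), summarize_continuous(perm, "v"))
})
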