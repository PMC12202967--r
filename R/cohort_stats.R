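# Cohort descriptive tables, sex comparisons, correlation, and test-retest
# reliability.

#' Summarise a categorical smile attribute
#'
#' Counts and percents per level, with the GRAND total as the percent
#' denominator (so percents across levels of one attribute sum to 100).
#' With a `sex` column present, per-sex counts and within-sex percents are
#' added along with the chi-square / Fisher association test.
#'
#' @param data Data frame with one row per subject.
#' @param attribute Name of the categorical column.
#' @param levels Optional level ordering (defaults to observed order).
#' @param grand_total Percent denominator (defaults to `nrow(data)`).
#' @return Tibble, one row per level, with an attribute `test` holding the
#'   sex-association test when computed.
#' @export
summarize_categorical <- function(data, attribute, levels = NULL,
                                  grand_total = nrow(data)) {
  if (grand_total <= 0) stop("grand_total must be positive")
  x <- data[[attribute]]
  if (is.null(x)) stop("no column named ", attribute)
  if (is.null(levels)) levels <- unique(x)
  if (!all(x %in% levels)) stop("value outside the attribute's domain")
  x <- factor(x, levels = levels)
  out <- tibble::tibble(
    attribute = attribute,
    level = levels,
    n = as.integer(table(x)),
    percent = as.numeric(table(x)) / grand_total * 100
  )
  test <- NULL
  if ("sex" %in% names(data) && length(unique(data$sex)) == 2) {
    for (s in sort(unique(data$sex))) {
      xs <- factor(x[data$sex == s], levels = levels)
      out[[paste0("n_", s)]] <- as.integer(table(xs))
      out[[paste0("percent_", s)]] <- as.numeric(table(xs)) / length(xs) * 100
    }
    tab <- table(x, data$sex)
    test <- tryCatch(categorical_sex_test(tab), error = function(e) NULL)
    if (!is.null(test)) out$p <- test$p
  }
  attr(out, "test") <- test
  out
}

#' Summarise a continuous variable
#'
#' Sample mean and n-1 standard deviation, overall and (optionally) by sex
#' with the Mann-Whitney comparison p-value.
#'
#' @param data Data frame with one row per subject.
#' @param variable Name of the numeric column.
#' @param by_sex Add per-sex rows and the between-sex test?
#' @return Tibble with columns `variable, group, n, mean, sd` (and `p` on
#'   the per-sex rows when computed).
#' @export
summarize_continuous <- function(data, variable, by_sex = FALSE) {
  x <- data[[variable]]
  if (is.null(x)) stop("no column named ", variable)
  if (length(x) < 2) stop("insufficient data: need >= 2 values")
  rows <- tibble::tibble(variable = variable, group = "total",
                         n = length(x), mean = mean(x), sd = stats::sd(x))
  if (by_sex) {
    if (!"sex" %in% names(data)) stop("no sex column for by-sex summary")
    groups <- split(x, data$sex)
    if (any(lengths(groups) < 2)) {
      stop("insufficient data: a sex group has < 2 values")
    }
    p <- if (length(groups) == 2) {
      continuous_sex_test(groups[[1]], groups[[2]])$p
    } else {
      NA_real_
    }
    for (s in names(groups)) {
      rows <- rbind(rows, tibble::tibble(
        variable = variable, group = s, n = length(groups[[s]]),
        mean = mean(groups[[s]]), sd = stats::sd(groups[[s]])))
    }
    rows$p <- c(NA_real_, rep(p, length(groups)))
  }
  rows
}

#' Chi-square or Fisher test for a categorical-by-sex table
#'
#' The chi-square test of independence (no continuity correction) is used
#' unless more than 33% of cells have expected frequencies below five, in
#' which case the Fisher exact test (generalised to r-by-c) is applied.
#'
#' @param contingency Matrix/table of non-negative integer counts with
#'   positive margins.
#' @return List `method` (`"chi_square"` or `"fisher"`), `statistic`
#'   (`NA` for Fisher) and `p`.
#' @export
categorical_sex_test <- function(contingency) {
  tab <- as.matrix(contingency)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a margin is zero")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (mean(expected < 5) > 0.33) {
    p <- stats::fisher.test(tab, workspace = 2e6)$p.value
    list(method = "fisher", statistic = NA_real_, p = p)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "chi_square", statistic = unname(ct$statistic),
         p = ct$p.value)
  }
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided comparison of distributions. The exact null distribution is
#' used when the combined sample size is at most 12 and there are no ties;
#' otherwise the normal approximation with tie-corrected variance (and no
#' continuity correction) is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `U` (the statistic for `group_a`) and `p`.
#' @export
continuous_sex_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  small <- length(group_a) + length(group_b) <= 12
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  wt <- if (small && !ties) {
    stats::wilcox.test(group_a, group_b, exact = TRUE)
  } else {
    suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = FALSE, correct = FALSE))
  }
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r` and `p` (t transform, n-2 degrees of freedom).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Test-retest intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement — the
#' conventional reliability coefficient for repeated digitisations of a
#' continuous measurement. Computed from the two-way ANOVA mean squares:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2
#' raters (sessions) and n subjects.
#'
#' @param measure_1,measure_2 Paired numeric vectors (length >= 3).
#' @return List with `icc` and the mean squares `msr`, `msc`, `mse`.
#' @export
test_retest_icc <- function(measure_1, measure_2) {
  if (length(measure_1) != length(measure_2)) {
    stop("test and retest vectors must have equal length")
  }
  n <- length(measure_1)
  if (n < 3) stop("need at least 3 subjects")
  k <- 2
  m <- cbind(measure_1, measure_2)
  grand <- mean(m)
  subj_means <- rowMeans(m)
  rater_means <- colMeans(m)
  ssr <- k * sum((subj_means - grand)^2)
  ssc <- n * sum((rater_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  list(icc = icc, msr = msr, msc = msc, mse = mse)
}
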