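test_that("pearson returns exact correlations for linear data", {
  x <- 1:10
  expect_equal(pearson_test(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_test(x, -x)$estimate, -1)
})

test_that("pearson matches the covariance-formula oracle", {
  set.seed(7)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  got <- pearson_test(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$estimate, r_oracle, tolerance = 1e-10)
  t_oracle <- r_oracle * sqrt(28 / (1 - r_oracle^2))
  expect_equal(got$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(t_oracle), 28), tolerance = 1e-12)
})

test_that("constant series have no defined correlation", {
  expect_error(pearson_test(rep(1, 5), 1:5),
               class = "finregen_undefined_correlation")
})

test_that("identical groups give F = 0 and p = 1", {
  d <- data.frame(value = rep(c(1, 2, 3), 3),
                  group = rep(c("a", "b", "c"), each = 3))
  d$value <- rep(c(1, 2, 3), times = 3)   # same values in every group
  got <- anova_oneway(d)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(10)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  d <- data.frame(value = c(a, b), group = rep(c("a", "b"), each = 12))
  f <- anova_oneway(d)$statistic
  t <- t_test_unpaired(a, b)$statistic
  expect_equal(f, t^2, tolerance = 1e-10)
})

test_that("ANOVA matches a brute-force sum-of-squares oracle", {
  set.seed(11)
  d <- data.frame(value = rnorm(30), group = rep(c("a", "b", "c"), each = 10))
  got <- anova_oneway(d)
  gs <- split(d$value, d$group)
  grand <- mean(d$value)
  ssb <- sum(sapply(gs, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(sapply(gs, function(g) sum((g - mean(g))^2)))
  f_oracle <- (ssb / 2) / (ssw / 27)
  expect_equal(got$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(got$p_value, pf(f_oracle, 2, 27, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ANOVA with zero total variance is flagged undefined", {
  d <- data.frame(value = rep(5, 9), group = rep(c("a", "b", "c"), each = 3))
  got <- anova_oneway(d)
  expect_true(is.nan(got$statistic))
  expect_true(is.na(got$p_value))
})

test_that("Tukey on identical groups returns p = 1 throughout", {
  d <- data.frame(value = rep(c(1, 2, 3), times = 3),
                  group = rep(c("a", "b", "c"), each = 3))
  got <- tukey_hsd(d)
  expect_equal(nrow(got), 3)
  expect_true(all(got$p_value > 0.999))
})

test_that("two-group Tukey equals the unpaired t test (q = t sqrt(2))", {
  set.seed(12)
  a <- rnorm(10); b <- rnorm(10, 1)
  d <- data.frame(value = c(a, b), group = rep(c("a", "b"), each = 10))
  tk <- tukey_hsd(d)
  tt <- t_test_unpaired(a, b)
  expect_equal(tk$statistic, abs(tt$statistic) * sqrt(2), tolerance = 1e-10)
  expect_equal(tk$p_value, tt$p_value, tolerance = 1e-8)
})

test_that("well-separated groups are all significant under Tukey", {
  set.seed(13)
  d <- data.frame(value = c(rnorm(10, 0, 0.2), rnorm(10, 3, 0.2), rnorm(10, 6, 0.2)),
                  group = rep(c("a", "b", "c"), each = 10))
  got <- tukey_hsd(d)
  expect_true(all(got$p_value < 0.001))
})

test_that("Tukey agrees with the base-R reference implementation", {
  set.seed(14)
  d <- data.frame(value = rnorm(24), group = rep(c("a", "b", "c"), each = 8))
  got <- tukey_hsd(d)
  ref <- TukeyHSD(aov(value ~ group, data = d))$group
  expect_equal(sort(got$p_value), sort(unname(ref[, "p adj"])), tolerance = 1e-8)
})

test_that("Tukey-adjusted p-values dominate the raw pairwise t-test p-values", {
  set.seed(15)
  for (i in 1:10) {
    d <- data.frame(value = rnorm(30), group = rep(c("a", "b", "c"), each = 10))
    tk <- tukey_hsd(d)
    gs <- split(d$value, d$group)
    raw <- c(t_test_unpaired(gs$a, gs$b)$p_value,
             t_test_unpaired(gs$a, gs$c)$p_value,
             t_test_unpaired(gs$b, gs$c)$p_value)
    expect_true(all(tk$p_value >= raw - 1e-10))
  }
})

test_that("t test honours the degenerate-variance limit convention", {
  expect_warning(null_case <- t_test_unpaired(c(1, 1, 1), c(1, 1, 1)),
                 "zero variance")
  expect_equal(null_case$p_value, 1)
  got <- suppressWarnings(t_test_unpaired(c(0, 0), c(1, 1)))
  expect_equal(got$p_value, 0)
  expect_true(is.infinite(got$statistic))
})

test_that("t test matches the textbook pooled formula", {
  set.seed(16)
  a <- rnorm(8); b <- rnorm(11, 0.4)
  got <- t_test_unpaired(a, b)
  sp2 <- (7 * var(a) + 10 * var(b)) / 17
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 8 + 1 / 11))
  expect_equal(got$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(got$df, 17)
  expect_equal(got$p_value, 2 * pt(-abs(t_oracle), 17), tolerance = 1e-12)
  welch <- t_test_unpaired(a, b, welch = TRUE)
  expect_equal(welch$p_value, t.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("t test on identical samples is exactly null", {
  a <- c(1.2, 1.5, 1.9)
  got <- t_test_unpaired(a, a)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
})

test_that("Grubbs flags a gross outlier using the closed-form critical value", {
  x <- c(1, 1.1, 0.9, 10)
  got <- grubbs_test(x)
  g_oracle <- max(abs(x - mean(x))) / sd(x)
  tcrit <- qt(1 - 0.05 / 8, df = 2)
  gcrit_oracle <- (3 / sqrt(4)) * sqrt(tcrit^2 / (2 + tcrit^2))
  expect_equal(got$statistic, g_oracle, tolerance = 1e-12)
  expect_equal(got$critical, gcrit_oracle, tolerance = 1e-12)
  expect_equal(got$outlier_index, 4L)
  expect_equal(got$outlier_value, 10)
})

test_that("Grubbs never flags without spread and flags at most one point", {
  expect_true(is.na(grubbs_test(c(1, 1, 1))$outlier_index))
  set.seed(17)
  for (i in 1:10) {
    got <- grubbs_test(rnorm(12))
    expect_lte(sum(!is.na(got$outlier_index)), 1)
  }
})

test_that("tied extremes test the first-encountered point", {
  x <- c(-8, 0, 0.1, -0.1, 0, 8)
  got <- grubbs_test(x)
  # both extremes deviate equally; the earlier index is the candidate
  g <- max(abs(x - mean(x))) / sd(x)
  expect_equal(got$statistic, g)
  if (!is.na(got$outlier_index)) expect_equal(got$outlier_index, 1L)
})
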