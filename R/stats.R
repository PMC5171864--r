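#' Pearson correlation test
#'
#' Product-moment correlation with the usual two-sided t test
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return One-row tibble: `method`, `estimate` (r), `r_squared`,
#'   `statistic`, `df`, `p_value`.
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("pearson_test needs n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant series",
          class = "finregen_undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(method = "Pearson correlation",
         estimate = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

# split a (data, value, group) call into a named list of numeric vectors
split_groups <- function(data, value, group) {
  data <- as_tibble(data)
  stopifnot(value %in% names(data), group %in% names(data))
  split(data[[value]], data[[group]])
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA, `F = MS_between / MS_within`.
#'
#' @param data Data frame in long format.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @return One-row tibble: `method`, `statistic` (F), `df_between`,
#'   `df_within`, `p_value`.  When both between- and within-group
#'   variances are zero, F is undefined: `statistic = NaN`, `p_value = NA`.
#' @export
anova_oneway <- function(data, value = "value", group = "group") {
  gs <- split_groups(data, value, group)
  if (length(gs) < 2 || any(lengths(gs) < 2)) {
    abort("anova_oneway needs >= 2 groups with n >= 2 each")
  }
  k <- length(gs); n <- sum(lengths(gs))
  grand <- mean(unlist(gs))
  ss_b <- sum(lengths(gs) * (vapply(gs, mean, 0) - grand)^2)
  ss_w <- sum(vapply(gs, function(g) sum((g - mean(g))^2), 0))
  if (ss_w == 0 && ss_b == 0) {
    return(tibble(method = "one-way ANOVA", statistic = NaN,
                  df_between = k - 1, df_within = n - k, p_value = NA_real_))
  }
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  tibble(method = "one-way ANOVA", statistic = f,
         df_between = k - 1, df_within = n - k,
         p_value = pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' Pairwise comparisons after one-way ANOVA.  The studentized-range
#' statistic uses the Tukey-Kramer form for unequal group sizes,
#' `q = |m_i - m_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))`, with p-values
#' from the studentized-range distribution.
#'
#' @inheritParams anova_oneway
#' @return Tibble with one row per pair: `group1`, `group2`, `diff`,
#'   `statistic` (q), `p_value` (adjusted).
#' @export
tukey_hsd <- function(data, value = "value", group = "group") {
  gs <- split_groups(data, value, group)
  if (length(gs) < 2 || any(lengths(gs) < 2)) {
    abort("tukey_hsd needs >= 2 groups with n >= 2 each")
  }
  k <- length(gs); n <- sum(lengths(gs))
  ms_w <- sum(vapply(gs, function(g) sum((g - mean(g))^2), 0)) / (n - k)
  means <- vapply(gs, mean, 0); ns <- lengths(gs); labs <- names(gs)
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- means[i] - means[j]
    se <- sqrt(ms_w / 2 * (1 / ns[i] + 1 / ns[j]))
    if (se == 0) {
      q <- if (d == 0) 0 else Inf
      pv <- if (d == 0) 1 else 0
    } else {
      q <- abs(d) / se
      pv <- ptukey(q, nmeans = k, df = n - k, lower.tail = FALSE)
    }
    tibble(group1 = labs[i], group2 = labs[j], diff = unname(d),
           statistic = unname(q), p_value = unname(pv))
  })
}

#' Unpaired two-sample t test
#'
#' Two-sided Student's t test with pooled variance by default (the
#' convention of classical group comparisons); set `welch = TRUE` for the
#' unequal-variance variant.  Degenerate samples with zero pooled variance
#' follow the limit convention: equal means give p = 1, unequal means give
#' p = 0 (logged with a warning).
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param welch Use Welch's correction (default `FALSE`).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `mean_diff` (`mean(a) - mean(b)`).
#' @export
t_test_unpaired <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) abort("t_test_unpaired needs n >= 2 per group")
  d <- mean(a) - mean(b)
  method <- if (welch) "Welch two-sample t test" else "pooled-variance t test"
  if (var(a) == 0 && var(b) == 0) {
    warn("zero variance in both samples; limit-convention p-value")
    return(tibble(method = method,
                  statistic = if (d == 0) 0 else sign(d) * Inf,
                  df = length(a) + length(b) - 2,
                  p_value = if (d == 0) 1 else 0, mean_diff = d))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  tibble(method = method, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value, mean_diff = d)
}

#' Grubbs' test for a single outlier
#'
#' Tests the observation farthest from the mean,
#' `G = max|x_i - mean| / sd`, against the critical value
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha/(2n)` quantile (two-sided; `alpha/n` one-sided) of
#' Student's t with `n - 2` df.  Applied once -- no iterative removal; at
#' most one point is flagged.  With tied extremes the first encountered is
#' tested.
#'
#' @param x Numeric vector, n >= 3.
#' @param alpha Significance level (default 0.05).
#' @param two_sided Default `TRUE`.
#' @return One-row tibble: `statistic` (G), `critical` (G_crit),
#'   `outlier_index`, `outlier_value` (NA when nothing is flagged), `n`.
#'   Zero spread returns the degenerate no-outlier result.
#' @export
grubbs_test <- function(x, alpha = 0.05, two_sided = TRUE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) abort("grubbs_test needs n >= 3")
  s <- sd(x)
  if (s == 0) {
    return(tibble(statistic = 0, critical = NA_real_,
                  outlier_index = NA_integer_, outlier_value = NA_real_, n = n))
  }
  dev <- abs(x - mean(x))
  idx <- which.max(dev)               # first-encountered extreme on ties
  g <- dev[idx] / s
  p_tail <- if (two_sided) alpha / (2 * n) else alpha / n
  tcrit <- qt(p_tail, df = n - 2, lower.tail = FALSE)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  flagged <- g > gcrit
  tibble(statistic = g, critical = gcrit,
         outlier_index = if (flagged) idx else NA_integer_,
         outlier_value = if (flagged) x[idx] else NA_real_, n = n)
}
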