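# Statistical comparisons between groups of per-variant metrics: Gaussian
# t-statistics with non-parametric tests in parallel, plus the
# Anscombe-Glynn kurtosis test of normality.

#' Unpaired comparison of two groups of per-variant metrics
#'
#' Welch two-sample t-test on the means, with a Wilcoxon rank-sum test as
#' the non-parametric parallel. When both groups are constant and equal the
#' comparison is degenerate and `p = 1` is reported.
#'
#' @param group1,group2 numeric vectors (each of length >= 2)
#' @return list: `t`, `p`, `p_ranksum`
#' @export
compare_groups_unpaired <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 values")
  if (sd(group1) == 0 && sd(group2) == 0) {
    if (mean(group1) == mean(group2))
      return(list(t = 0, p = 1, p_ranksum = 1))
    return(list(t = Inf * sign(mean(group1) - mean(group2)), p = 0,
                p_ranksum = suppressWarnings(
                  wilcox.test(group1, group2, exact = FALSE)$p.value)))
  }
  tt <- t.test(group1, group2)
  wt <- suppressWarnings(wilcox.test(group1, group2, exact = FALSE))
  list(t = unname(tt$statistic), p = tt$p.value, p_ranksum = wt$p.value)
}

#' Paired comparison of a metric under two conditions
#'
#' Paired t-test on the per-variant differences with a Wilcoxon signed-rank
#' test in parallel. All-zero differences give `p = 1`; constant non-zero
#' differences are a degenerate zero-variance separation, reported as
#' `p = 0` with `degenerate = TRUE`.
#'
#' @param cond1,cond2 aligned numeric vectors (>= 2 pairs)
#' @return list: `t`, `p`, `p_signedrank`, `degenerate`
#' @export
compare_groups_paired <- function(cond1, cond2) {
  keep <- !is.na(cond1) & !is.na(cond2)
  d <- cond1[keep] - cond2[keep]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  if (all(d == 0)) return(list(t = 0, p = 1, p_signedrank = 1,
                               degenerate = FALSE))
  if (sd(d) == 0)
    return(list(t = Inf * sign(d[1]), p = 0, p_signedrank = NA_real_,
                degenerate = TRUE))
  tt <- t.test(d)
  wt <- suppressWarnings(wilcox.test(d, exact = FALSE))
  list(t = unname(tt$statistic), p = tt$p.value,
       p_signedrank = wt$p.value, degenerate = FALSE)
}

#' Anscombe-Glynn test of kurtosis
#'
#' Tests departure of the sample kurtosis from its normal-theory
#' expectation via the Anscombe-Glynn transformation to an approximately
#' standard normal statistic; two-sided p-value. Requires n >= 20 for the
#' approximation to hold.
#'
#' @param x numeric vector, n >= 20, non-constant
#' @return list: `z`, `p`, `kurtosis` (the b2 sample statistic)
#' @export
kurtosis_normality_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20L) stop("Anscombe-Glynn approximation requires n >= 20")
  if (sd(x) == 0) stop("kurtosis undefined for constant input")
  xc <- x - mean(x)
  b2 <- n * sum(xc^4) / sum(xc^2)^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  m3 <- (6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9))) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + (8 / m3) * (2 / m3 + sqrt(1 + 4 / m3^2))
  xx <- (b2 - eb2) / sqrt(vb2)
  z <- (1 - 2 / (9 * a) -
          ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE), kurtosis = b2)
}

#' One-sample sign test for a positive (or negative) median
#'
#' Exact binomial sign test on the signs of `x`, ignoring exact zeros.
#'
#' @param x numeric vector
#' @param alternative "greater", "less" or "two.sided"
#' @return p-value
#' @export
sign_test <- function(x, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x) & x != 0]
  if (!length(x)) return(1)
  binom.test(sum(x > 0), length(x), p = 0.5,
             alternative = alternative)$p.value
}
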