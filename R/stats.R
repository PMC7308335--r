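#' Two-tailed Fisher exact test for a 2x2 table
#'
#' The default `"point"` method sums, over all tables with the observed
#' margins, the hypergeometric point probabilities that do not exceed the
#' observed table's (the classical minimum-likelihood two-tailed rule, as
#' implemented by [stats::fisher.test()]). `"doubling"` doubles the smaller
#' one-sided tail and caps at 1.
#'
#' @param table A 2x2 matrix of nonnegative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @param method `"point"` (default) or `"doubling"`.
#' @return A one-row tibble with columns `p` and `method`.
#' @export
#' @examples
#' fisher_exact_two_tailed(matrix(c(10, 2, 11, 7), 2, byrow = TRUE))
fisher_exact_two_tailed <- function(table, method = c("point", "doubling")) {
  method <- match.arg(method)
  if (is.vector(table) && length(table) == 4) {
    table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  }
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != round(table))) {
    abort("table must be a 2x2 matrix of nonnegative integer counts")
  }
  if (sum(table) == 0) abort("all-zero table")
  p <- if (method == "point") {
    stats::fisher.test(table, alternative = "two.sided")$p.value
  } else {
    lo <- stats::fisher.test(table, alternative = "less")$p.value
    hi <- stats::fisher.test(table, alternative = "greater")$p.value
    min(1, 2 * min(lo, hi))
  }
  tibble(p = min(1, p), method = method)
}

#' Exact binomial and Poisson tail probabilities
#'
#' Upper tails are `P(X >= k)`, lower tails `P(X <= k)`; sums are carried out
#' in log space by the underlying distribution functions, so tails are stable
#' up to rates of 1e4 and beyond. The Poisson tail is the small-`p` limit used
#' when only an expected count (not a trial number) is known.
#'
#' @param k Observed count.
#' @param n Number of trials.
#' @param p Success probability.
#' @param lambda Poisson mean.
#' @return A probability.
#' @export
#' @examples
#' binomial_upper_tail(15, 30, 7.6 / 30)
#' poisson_upper_tail(15, 7.6)
binomial_upper_tail <- function(k, n, p) {
  stopifnot(k >= 0, k <= n, p >= 0, p <= 1)
  if (k == 0) {
    return(1)
  }
  exp(stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE))
}

#' @rdname binomial_upper_tail
#' @export
binomial_lower_tail <- function(k, n, p) {
  stopifnot(k >= -1, p >= 0, p <= 1)
  if (k < 0) {
    return(0)
  }
  exp(stats::pbinom(k, n, p, log.p = TRUE))
}

#' @rdname binomial_upper_tail
#' @export
poisson_upper_tail <- function(k, lambda) {
  stopifnot(k >= 0, lambda >= 0)
  if (k == 0) {
    return(1)
  }
  exp(stats::ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE))
}

#' Continuity-corrected Z-score
#'
#' `(observed - expected -/+ continuity) / sd`, corrected toward zero, and 0
#' when `|observed - expected| <= continuity`.
#'
#' @param observed,expected Observed and expected counts.
#' @param sd Standard deviation of the background distribution (> 0).
#' @param continuity Continuity correction (default 0.5).
#' @return The signed Z-score.
#' @export
#' @examples
#' z_score(15, 7.6, sqrt(7.6))
z_score <- function(observed, expected, sd, continuity = 0.5) {
  if (sd <= 0) abort("sd must be positive")
  d <- observed - expected
  if (abs(d) <= continuity) {
    return(0)
  }
  (d - sign(d) * continuity) / sd
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact enumeration (via the exact null distribution of U) when
#' `n_a + n_b <= 12` and the pooled values carry no ties; otherwise the normal
#' approximation with tie and continuity corrections. A fully degenerate
#' comparison (all pooled values identical) returns p = 1.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @return A one-row tibble with columns `u` (U statistic of `group_a`), `p`
#'   and `mode` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))
mann_whitney_two_tailed <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be nonempty")
  }
  pooled <- c(group_a, group_b)
  has_ties <- any(duplicated(pooled))
  exact <- (length(pooled) <= 12) && !has_ties
  u <- unname(stats::wilcox.test(group_a, group_b, exact = FALSE)$statistic)
  if (length(unique(pooled)) == 1) {
    return(tibble(u = u, p = 1, mode = "normal_approx"))
  }
  p <- suppressWarnings(stats::wilcox.test(
    group_a, group_b,
    alternative = "two.sided", exact = exact, correct = TRUE
  )$p.value)
  if (is.nan(p)) p <- 1
  tibble(u = u, p = min(1, p), mode = if (exact) "exact" else "normal_approx")
}

#' Median-based fold change
#'
#' The standard median-based convention: a single group's median divided by the reference
#' median; when two groups are compared against one, the mean of their two
#' medians divided by the reference median.
#'
#' @param medians_group1 One or two group medians.
#' @param median_group2 Reference median (> 0).
#' @return The fold change.
#' @export
#' @examples
#' fold_change(c(4000, 3900), 1000)
fold_change <- function(medians_group1, median_group2) {
  if (median_group2 <= 0) abort("reference median must be positive")
  if (!length(medians_group1) %in% c(1, 2)) {
    abort("medians_group1 must hold one or two medians")
  }
  mean(medians_group1) / median_group2
}
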