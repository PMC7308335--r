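#' Per-sample repertoire summary metrics
#'
#' Richness (clonotype count after the cutoff), the functional/non-functional
#' and D1/D2 usage ratios, the median CDR3 length and the mean truncation and
#' N-region lengths. All quantities are computed over clonotypes by default
#' (`weight = "clonotype"`); `weight = "read"` weights every clonotype by its
#' read count instead. Ratios with a zero denominator are returned as `NA`
#' (undefined), never as an error.
#'
#' @param clonotypes Clonotype tibble with architecture columns (see
#'   [profile_repertoire()]); a truth table from [simulate_repertoire()]
#'   works directly.
#' @param sample_name Optional sample label (taken from a `sample` column if
#'   present).
#' @param weight `"clonotype"` (default) or `"read"`.
#' @return A one-row tibble of metrics.
#' @export
summarize_repertoire <- function(clonotypes, sample_name = NULL,
                                 weight = c("clonotype", "read")) {
  weight <- match.arg(weight)
  w <- if (weight == "read" && "read_count" %in% names(clonotypes)) {
    as.numeric(clonotypes$read_count)
  } else {
    rep(1, nrow(clonotypes))
  }
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  wmean <- function(x, wt = w) {
    keep <- !is.na(x)
    if (!any(keep)) {
      return(NA_real_)
    }
    sum(x[keep] * wt[keep]) / sum(wt[keep])
  }
  wmedian <- function(x, wt = w) {
    keep <- !is.na(x)
    if (!any(keep)) {
      return(NA_real_)
    }
    ord <- order(x[keep])
    xs <- x[keep][ord]
    ws <- wt[keep][ord]
    cw <- cumsum(ws) / sum(ws)
    xs[which(cw >= 0.5)[1]]
  }
  is_d1 <- !is.na(clonotypes$d_name) & grepl("D1", clonotypes$d_name)
  is_d2 <- !is.na(clonotypes$d_name) & grepl("D2", clonotypes$d_name)
  n_len <- clonotypes$n1_len +
    ifelse(is.na(clonotypes$n2_len), 0L, clonotypes$n2_len)
  tibble(
    sample = sample_name %||% (if ("sample" %in% names(clonotypes)) {
      clonotypes$sample[1]
    } else {
      NA_character_
    }),
    richness = nrow(clonotypes),
    functional_ratio = safe_ratio(
      sum(w[clonotypes$functional]), sum(w[!clonotypes$functional])
    ),
    d1_d2_ratio = safe_ratio(sum(w[is_d1]), sum(w[is_d2])),
    d2_fraction = safe_ratio(sum(w[is_d2]), sum(w[is_d1 | is_d2])),
    median_cdr3_len = wmedian(clonotypes$cdr3_len),
    mean_v_trunc = wmean(clonotypes$v_trunc),
    mean_j_trunc = wmean(clonotypes$j_trunc),
    mean_d5_trunc = wmean(clonotypes$d5_trunc),
    mean_d3_trunc = wmean(clonotypes$d3_trunc),
    mean_n_len = wmean(n_len)
  )
}

#' Compare repertoire metrics between groups
#'
#' For every metric and every pair of groups: group medians, the two-tailed
#' Mann-Whitney U test and the median-based fold change (`median_a /
#' median_b`). Raw p-values are reported unadjusted; a Benjamini-Hochberg
#' column (`p_bh`, across all rows) is added for convenience.
#'
#' @param metrics Tibble of per-sample metrics ([summarize_repertoire()] rows).
#' @param design Tibble with columns `sample` and `group`.
#' @return A `vdj_comparison` tibble: one row per metric per ordered group
#'   pair.
#' @export
compare_groups <- function(metrics, design) {
  if (!all(c("sample", "group") %in% names(design))) {
    abort("design needs columns sample and group")
  }
  unknown <- setdiff(metrics$sample, design$sample)
  if (length(unknown) > 0) {
    abort(sprintf("sample without group label: %s", unknown[1]))
  }
  m <- dplyr::inner_join(metrics, design, by = "sample")
  groups <- sort(unique(design$group))
  if (length(groups) < 2) abort("need at least 2 groups")
  sizes <- table(m$group)
  if (any(sizes < 2)) {
    abort(sprintf(
      "group with fewer than 2 samples: %s", names(sizes)[sizes < 2][1]
    ))
  }
  metric_cols <- setdiff(
    names(metrics)[vapply(metrics, is.numeric, logical(1))], "sample"
  )
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (metric in metric_cols) {
    for (pr in pairs) {
      a <- m[[metric]][m$group == pr[1]]
      b <- m[[metric]][m$group == pr[2]]
      a <- a[!is.na(a)]
      b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) next
      mw <- mann_whitney_two_tailed(a, b)
      med_a <- stats::median(a)
      med_b <- stats::median(b)
      rows[[length(rows) + 1]] <- tibble(
        metric = metric, group_a = pr[1], group_b = pr[2],
        n_a = length(a), n_b = length(b),
        median_a = med_a, median_b = med_b,
        fold = if (med_b > 0) med_a / med_b else NA_real_,
        u = mw$u, p = mw$p, mode = mw$mode
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("vdj_comparison", class(out))
  out
}

#' Fold change of two pooled groups against a reference group
#'
#' The two-vs-one convention: the mean of the two group medians
#' divided by the reference group's median (see [fold_change()]).
#'
#' @param metrics,design As in [compare_groups()].
#' @param metric Metric column name.
#' @param numerator_groups Two group labels.
#' @param denominator_group Reference group label.
#' @return The fold change.
#' @export
pooled_fold_change <- function(metrics, design, metric,
                               numerator_groups, denominator_group) {
  m <- dplyr::inner_join(metrics, design, by = "sample")
  meds <- vapply(
    numerator_groups,
    function(g) stats::median(m[[metric]][m$group == g], na.rm = TRUE),
    numeric(1)
  )
  ref <- stats::median(
    m[[metric]][m$group == denominator_group],
    na.rm = TRUE
  )
  fold_change(meds, ref)
}
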