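#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment result
#'
#' @param x A `vdj_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble with the observed/expected counts, fold, Z-score
#'   and tail probability.
#' @method tidy vdj_enrichment
#' @export
tidy.vdj_enrichment <- function(x, ...) {
  tibble(
    observed = x$observed, n_foreground = x$n_foreground,
    background_rate = x$background_rate, expected = x$expected,
    fold = x$fold, z = x$z, p_binomial = x$p_binomial,
    method = x$method
  )
}

#' @rdname tidy.vdj_enrichment
#' @method glance vdj_enrichment
#' @export
glance.vdj_enrichment <- function(x, ...) {
  tibble(
    fold = x$fold, z = x$z, p_binomial = x$p_binomial,
    significant = is.finite(x$z) && x$z > 2
  )
}
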