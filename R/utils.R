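#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("CACTGTG")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  !is.na(x) & nzchar(x) & grepl(pat, x)
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  bad <- which(!is_dna(x, allow_n = allow_n))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s must be non-empty uppercase %s (offending element %d: %s)",
      what, if (allow_n) "A/C/G/T/N" else "A/C/G/T", bad[1],
      substr(x[bad[1]], 1, 30)
    ))
  }
  invisible(x)
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators are pure in (params, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Length of the overlap of two half-open intervals.
interval_overlap <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2))
}

# Merge half-open intervals that overlap by >= 1 nt. Returns a tibble with
# start/end and a list-column of member indices (row numbers of the input).
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) {
    return(tibble(start = integer(), end = integer(), members = list()))
  }
  ord <- order(start, end)
  start <- start[ord]
  end <- end[ord]
  grp <- integer(length(start))
  grp[1] <- 1L
  cur_end <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] < cur_end) {       # >= 1 nt overlap (half-open)
      grp[i] <- grp[i - 1]
      cur_end <- max(cur_end, end[i])
    } else {
      grp[i] <- grp[i - 1] + 1L
      cur_end <- end[i]
    }
  }
  tibble(
    start = as.integer(tapply(start, grp, min)),
    end = as.integer(tapply(end, grp, max)),
    members = unname(split(ord, grp))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
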