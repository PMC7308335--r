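#' Build a positional weight matrix from seed sequences
#'
#' Per-position base frequencies are `(count + pseudocount) / (n + 4 *
#' pseudocount)`; the per-position information weight is `2 + sum_b f log2 f`
#' bits (0 log 0 := 0). Duplicate seeds are collapsed before counting, so at
#' least two *unique* seeds are required.
#'
#' @param seeds Character vector of equal-length A/C/G/T strings.
#' @param pseudocount Pseudocount added per base (default 0.01).
#' @param name Matrix label.
#' @return An object of class `pwm`: list with `name`, `width`, `freqs`
#'   (4 x width, rows A/C/G/T), `weights` (bits), `max_col_freq`.
#' @export
#' @examples
#' pwm <- build_pwm(c("CACAGTG", "CACAATG", "CACTGTG"), name = "heptamer")
#' pwm_consensus(pwm)
build_pwm <- function(seeds, pseudocount = 0.01, name = "pwm") {
  seeds <- unique(toupper(seeds))
  if (length(seeds) < 2) abort("build_pwm needs at least 2 unique seeds")
  assert_dna(seeds, "seed")
  widths <- unique(nchar(seeds))
  if (length(widths) != 1) abort("seeds must all have the same length")
  w <- widths
  if (w < 4) abort("matrix width must be >= 4")
  mat <- do.call(rbind, strsplit(seeds, ""))
  counts <- vapply(
    seq_len(w),
    function(i) tabulate(match(mat[, i], DNA_BASES), nbins = 4),
    numeric(4)
  )
  rownames(counts) <- DNA_BASES
  freqs <- (counts + pseudocount) / (length(seeds) + 4 * pseudocount)
  plogp <- freqs * log2(freqs)
  plogp[freqs == 0] <- 0
  weights <- 2 + colSums(plogp)
  structure(
    list(
      name = name, width = w, freqs = freqs,
      weights = weights, max_col_freq = apply(freqs, 2, max)
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> %s  width %d  consensus %s  information %.2f bits\n",
    x$name, x$width, pwm_consensus(x), sum(x$weights)
  ))
  invisible(x)
}

#' @rdname build_pwm
#' @param pwm A `pwm` object.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freqs, 2, which.max)], collapse = "")
}

#' Normalised matrix similarity of windows
#'
#' The information-weighted similarity `sum_i w_i f_i(base_i) / sum_i w_i
#' max_b f_i(b)`, in \[0, 1\]; 1 is attained exactly by the per-position
#' argmax consensus. Windows containing non-ACGT characters, and any window
#' against an all-zero-weight matrix, score 0.
#'
#' @param pwm A `pwm` object.
#' @param window Character vector of windows, each of the matrix width.
#' @return Numeric vector of similarity scores.
#' @export
similarity <- function(pwm, window) {
  window <- toupper(window)
  if (any(nchar(window) != pwm$width)) {
    abort(sprintf("window length must equal matrix width (%d)", pwm$width))
  }
  denom <- sum(pwm$weights * pwm$max_col_freq)
  if (denom <= 0) {
    return(rep(0, length(window)))
  }
  wf <- sweep(pwm$freqs, 2, pwm$weights, `*`) # 4 x width
  mat <- do.call(rbind, strsplit(window, ""))
  code <- matrix(match(mat, DNA_BASES), nrow = nrow(mat))
  num <- rowSums(
    matrix(wf[cbind(as.vector(code), rep(seq_len(pwm$width), each = nrow(code)))],
      nrow = nrow(code)
    )
  )
  score <- num / denom
  score[is.na(score)] <- 0
  score
}

# Score every window start of `seq_int` (integer-coded sequence, NA for
# non-ACGT) against the matrix. Returns numeric vector of length L - w + 1.
score_windows <- function(seq_int, pwm) {
  L <- length(seq_int)
  w <- pwm$width
  n <- L - w + 1L
  if (n < 1) {
    return(numeric(0))
  }
  denom <- sum(pwm$weights * pwm$max_col_freq)
  if (denom <= 0) {
    return(rep(0, n))
  }
  wf <- sweep(pwm$freqs, 2, pwm$weights, `*`)
  s <- numeric(n)
  for (i in seq_len(w)) {
    s <- s + wf[cbind(seq_int[i:(i + n - 1L)], i)]
  }
  s <- s / denom
  s[is.na(s)] <- 0
  s
}

encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
}

# complement codes (A<->T, C<->G) and reverse; NA (non-ACGT) preserved
revcomp_encoded <- function(enc) {
  rev(c(4L, 3L, 2L, 1L)[enc])
}

scan_pwm_encoded <- function(enc, pwm, threshold, strands, L) {
  hits <- list()
  if (strands %in% c("both", "+")) {
    s <- score_windows(enc, pwm)
    keep <- which(s >= threshold)
    hits$plus <- tibble(
      start = keep - 1L, end = keep - 1L + pwm$width,
      strand = rep("+", length(keep)), score = s[keep]
    )
  }
  if (strands %in% c("both", "-")) {
    s <- score_windows(revcomp_encoded(enc), pwm)
    keep <- which(s >= threshold)
    start_plus <- L - (keep - 1L) - pwm$width
    hits$minus <- tibble(
      start = start_plus, end = start_plus + pwm$width,
      strand = rep("-", length(keep)), score = s[keep]
    )
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(
      start = integer(), end = integer(),
      strand = character(), score = numeric()
    )
  }
  out$matrix_name <- rep(pwm$name, nrow(out))
  out[order(out$start, out$strand), ]
}

#' Scan a sequence with a matrix on both strands
#'
#' Every window with similarity at or above `threshold` is emitted. Minus
#' strand hits are scored on the reverse complement but reported in plus-strand
#' 0-based half-open coordinates; output is sorted by (start, strand).
#'
#' @param sequence A DNA string (non-ACGT characters nullify the windows that
#'   contain them).
#' @param pwm A `pwm` object.
#' @param threshold Minimum similarity (default 0.8).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return Tibble with columns `start`, `end`, `strand`, `score`,
#'   `matrix_name`.
#' @export
scan_pwm <- function(sequence, pwm, threshold = 0.8, strands = "both") {
  stopifnot(length(sequence) == 1)
  scan_pwm_encoded(
    encode_dna(sequence), pwm, threshold, strands, nchar(sequence)
  )
}

#' Scan a set of regions with a matrix
#'
#' @param regions Regions tibble (see [read_regions()]); row order defines
#'   `region_id`.
#' @inheritParams scan_pwm
#' @return Hit tibble as [scan_pwm()] with a leading `region_id` column of
#'   offsets *within* each region.
#' @export
scan_regions <- function(regions, pwm, threshold = 0.8, strands = "both") {
  hits <- purrr::map(seq_len(nrow(regions)), function(i) {
    h <- scan_pwm(regions$sequence[i], pwm, threshold, strands)
    h$region_id <- rep(i, nrow(h))
    h
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(
      region_id = integer(), start = integer(), end = integer(),
      strand = character(), score = numeric(), matrix_name = character()
    ))
  }
  dplyr::select(
    out, "region_id", "start", "end", "strand", "score", "matrix_name"
  )
}

#' Packaged default matrices
#'
#' Heptamer and nonamer matrices are built from canonical CACAGTG- /
#' ACAAAAACC-family recombination signal sequences of the D-segment 3' RSS and
#' J-segment 5' RSS of the TCRB/TCRD/IGH loci (two matrices each, reflecting
#' the two seed families). The RUNX1 matrix is an 11-column matrix around the
#' TGTGG core with lower-information flanks; any user matrix in the same
#' format can replace it via [read_pwm()].
#'
#' @return `default_heptamer_pwms()` and `default_nonamer_pwms()` return named
#'   lists of two `pwm` objects; `default_runx1_pwm()` a single `pwm`.
#' @export
default_heptamer_pwms <- function() {
  list(
    hept_d3 = build_pwm(
      c("CACAGTG", "CACAATG", "CACGGTG", "CACAGTA", "CACAGCG"),
      name = "hept_d3"
    ),
    hept_j5 = build_pwm(
      c("CACAGTG", "CACTGTG", "CACAGTT", "CACAATG"),
      name = "hept_j5"
    )
  )
}

#' @rdname default_heptamer_pwms
#' @export
default_nonamer_pwms <- function() {
  list(
    non_d3 = build_pwm(
      c("ACAAAAACC", "ACAAAAACA", "GCAAAAACC", "ACATAAACC", "ACAAGAACC"),
      name = "non_d3"
    ),
    non_j5 = build_pwm(
      c("GGTTTTTGT", "AGTTTTTGT", "GGTTTCTGT", "GGCTTTTGT"),
      name = "non_j5"
    )
  )
}

#' @rdname default_heptamer_pwms
#' @export
default_runx1_pwm <- function() {
  build_pwm(
    c(
      "TGTGGTTTGTC", "TGTGGTTCGTC", "TGTGGTTTGTT", "TGTGGCTTGTC",
      "TGTGGTTTATC", "TGCGGTTTGTC", "TGTGGTTTGCA", "AGTGGTTTGTC"
    ),
    name = "RUNX1"
  )
}

#' Composite RSS models
#'
#' The eight heptamer-spacer-nonamer models: 2 heptamer matrices x 2 nonamer
#' matrices x 2 spacer classes (12+/-1 bp, 23+/-1 bp).
#'
#' @param heptamers,nonamers Named lists of `pwm` objects (defaults packaged).
#' @param spacer_classes List of `c(min, max)` spacer ranges.
#' @return Named list of models, each a list with `name`, `heptamer`,
#'   `nonamer`, `spacer_min`, `spacer_max`.
#' @export
rss_models <- function(heptamers = default_heptamer_pwms(),
                       nonamers = default_nonamer_pwms(),
                       spacer_classes = list(c(11L, 13L), c(22L, 24L))) {
  models <- list()
  for (h in names(heptamers)) {
    for (n in names(nonamers)) {
      for (sc in spacer_classes) {
        nm <- sprintf("%s_%s_s%d", h, n, as.integer(mean(sc)))
        models[[nm]] <- list(
          name = nm, heptamer = heptamers[[h]], nonamer = nonamers[[n]],
          spacer_min = sc[1], spacer_max = sc[2]
        )
      }
    }
  }
  models
}

#' Scan a sequence for RSS modules
#'
#' A module hit pairs a heptamer hit with a nonamer hit on the same strand at
#' a spacer distance inside the model's class, the nonamer lying distal to the
#' heptamer's 3' side (downstream on the plus strand, upstream in plus
#' coordinates for minus-strand modules). Hits are deduplicated by (heptamer
#' start, strand, model), keeping the best-scoring nonamer partner.
#'
#' @param sequence DNA string.
#' @param models List of models from [rss_models()].
#' @param threshold_heptamer,threshold_nonamer Similarity thresholds.
#' @return Tibble with columns `model`, `strand`, `hept_start`, `hept_end`,
#'   `hept_score`, `non_start`, `non_end`, `non_score`, `spacer_len`.
#' @export
scan_rss_modules <- function(sequence, models = rss_models(),
                             threshold_heptamer = 0.8,
                             threshold_nonamer = 0.8) {
  hept_mats <- unique(purrr::map_chr(models, ~ .x$heptamer$name))
  non_mats <- unique(purrr::map_chr(models, ~ .x$nonamer$name))
  all_pwms <- c(
    purrr::map(models, "heptamer"), purrr::map(models, "nonamer")
  )
  pwm_by_name <- list()
  for (p in all_pwms) pwm_by_name[[p$name]] <- p
  enc <- encode_dna(sequence)
  L <- nchar(sequence)
  hept_hits <- purrr::map(
    hept_mats,
    ~ scan_pwm_encoded(enc, pwm_by_name[[.x]], threshold_heptamer, "both", L)
  )
  names(hept_hits) <- hept_mats
  non_hits <- purrr::map(
    non_mats,
    ~ scan_pwm_encoded(enc, pwm_by_name[[.x]], threshold_nonamer, "both", L)
  )
  names(non_hits) <- non_mats

  out <- purrr::map(models, function(m) {
    hh <- hept_hits[[m$heptamer$name]]
    nh <- non_hits[[m$nonamer$name]]
    if (nrow(hh) == 0 || nrow(nh) == 0) {
      return(NULL)
    }
    pairs <- dplyr::inner_join(
      dplyr::rename(hh,
        hept_start = "start", hept_end = "end", hept_score = "score"
      ),
      dplyr::rename(nh,
        non_start = "start", non_end = "end", non_score = "score"
      ),
      by = "strand", relationship = "many-to-many"
    )
    if (nrow(pairs) == 0) {
      return(NULL)
    }
    pairs$spacer_len <- ifelse(
      pairs$strand == "+",
      pairs$non_start - pairs$hept_end,
      pairs$hept_start - pairs$non_end
    )
    pairs <- dplyr::filter(
      pairs, .data$spacer_len >= m$spacer_min, .data$spacer_len <= m$spacer_max
    )
    if (nrow(pairs) == 0) {
      return(NULL)
    }
    pairs$model <- m$name
    pairs
  })
  out <- dplyr::bind_rows(out)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      model = character(), strand = character(),
      hept_start = integer(), hept_end = integer(), hept_score = numeric(),
      non_start = integer(), non_end = integer(), non_score = numeric(),
      spacer_len = integer()
    ))
  }
  out <- out[order(
    out$hept_start, out$strand, out$model, -out$non_score, out$spacer_len
  ), ]
  out <- out[!duplicated(paste(out$hept_start, out$strand, out$model)), ]
  out[, c(
    "model", "strand", "hept_start", "hept_end", "hept_score",
    "non_start", "non_end", "non_score", "spacer_len"
  )]
}

#' @rdname scan_rss_modules
#' @param regions Regions tibble; row order defines `region_id`.
#' @inheritParams scan_rss_modules
#' @export
scan_rss_modules_regions <- function(regions, models = rss_models(),
                                     threshold_heptamer = 0.8,
                                     threshold_nonamer = 0.8) {
  hits <- purrr::map(seq_len(nrow(regions)), function(i) {
    h <- scan_rss_modules(
      regions$sequence[i], models, threshold_heptamer, threshold_nonamer
    )
    h$region_id <- rep(i, nrow(h))
    h
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- scan_rss_modules("AAAA")
    out$region_id <- integer()
  }
  dplyr::relocate(out, "region_id")
}

#' Read and write matrix files
#'
#' Plain-text format: a `>name<TAB>width` header followed by four
#' tab-separated rows (A, C, G, T) of per-position frequencies.
#'
#' @param pwm A `pwm` object.
#' @param path File path.
#' @return `read_pwm()` returns a `pwm`; `write_pwm()` its path, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">%s\t%d", pwm$name, pwm$width), con)
  for (b in DNA_BASES) {
    writeLines(
      paste(c(b, format(pwm$freqs[b, ], digits = 17)), collapse = "\t"), con
    )
  }
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5 || !startsWith(lines[1], ">")) {
    abort(sprintf("not a matrix file: %s", path))
  }
  hdr <- strsplit(sub("^>", "", lines[1]), "\t")[[1]]
  name <- hdr[1]
  rows <- strsplit(lines[2:5], "\t")
  bases <- vapply(rows, `[`, character(1), 1)
  if (!identical(bases, DNA_BASES)) abort("matrix rows must be A, C, G, T")
  freqs <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(freqs) <- DNA_BASES
  if (any(abs(colSums(freqs) - 1) > 1e-6)) {
    abort("matrix columns must sum to 1")
  }
  plogp <- freqs * log2(freqs)
  plogp[freqs == 0] <- 0
  structure(
    list(
      name = name, width = ncol(freqs), freqs = freqs,
      weights = 2 + colSums(plogp), max_col_freq = apply(freqs, 2, max)
    ),
    class = "pwm"
  )
}

#' Planted-site sequence templates
#'
#' Consensus-based templates used by the genome and deletion-cohort
#' simulators: a full RSS (heptamer + 12-bp spacer + nonamer), a
#' RUNX1-overlapping heptamer (`CACTGTG` heptamer on the minus strand whose
#' last four bases start the plus-strand RUNX1 consensus), the same embedded
#' in an RSS module, a lone heptamer, a lone RUNX1 site with neutral flanks,
#' and a partial-heptamer arrangement (RUNX1 + GTG flank + spacer + nonamer).
#'
#' @return Named character vector of templates with attribute
#'   `runx1_offset` (0-based offset of the RUNX1 site within each template,
#'   NA where absent).
#' @export
rss_site_templates <- function() {
  spacer12 <- "TCTAGATCGATA"
  tpl <- c(
    rss = paste0("CACAGTG", spacer12, "ACAAAAACC"),
    runx1_heptamer = "CACTGTGGTTTGTC",
    runx1_rss = paste0("GGTTTTTGT", spacer12, "CACTGTGGTTTGTC"),
    lone_heptamer = "CACAGTG",
    runx1_only = "GGATGTGGTTTGTCAAA",
    runx1_partial = paste0("TGTGGTTTGTC", "GTG", spacer12, "ACAAAAACC")
  )
  attr(tpl, "runx1_offset") <- c(
    rss = NA_integer_, runx1_heptamer = 3L, runx1_rss = 24L,
    lone_heptamer = NA_integer_, runx1_only = 3L, runx1_partial = 0L
  )
  tpl
}
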