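#' Join a read pair into a consensus sequence
#'
#' Finds the best ungapped overlap between R1 and the reverse complement of
#' R2 (R1 left, R2 right): among overlap offsets with overlap length at least
#' `min_overlap` and mismatch fraction at most `max_mismatch_frac`, the one
#' with the most matching bases wins (ties broken by the longer overlap, then
#' the smaller offset). At each overlap mismatch the base with the higher
#' quality is taken; on a quality tie, R1's base. Rejection is returned as
#' `NA`, not an error.
#'
#' @param seq1,seq2 R1 and R2 sequences (R2 as read, i.e. reverse strand).
#' @param qual1,qual2 Integer Phred quality vectors.
#' @param min_overlap Minimum overlap length (default 10).
#' @param max_mismatch_frac Maximum overlap mismatch fraction (default 0.25).
#' @return The joined consensus string, or `NA_character_` on rejection.
#' @export
join_read_pair <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                           min_overlap = 10L, max_mismatch_frac = 0.25) {
  if (nchar(seq1) == 0 || nchar(seq2) == 0) abort("reads must be nonempty")
  f2 <- revcomp(seq2)
  q1 <- qual1 %||% rep(30L, nchar(seq1))
  q2 <- rev(qual2 %||% rep(30L, nchar(seq2))) # orient qualities with f2
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(f2, "")[[1]]
  n1 <- length(a)
  n2 <- length(b)
  best <- NULL
  for (off in 0:(n1 - min_overlap)) {
    ov <- min(n1 - off, n2)
    if (ov < min_overlap) next
    ia <- (off + 1):(off + ov)
    ib <- 1:ov
    matches <- sum(a[ia] == b[ib])
    mm <- ov - matches
    if (mm / ov > max_mismatch_frac) next
    cand <- list(off = off, ov = ov, matches = matches)
    if (is.null(best) ||
      cand$matches > best$matches ||
      (cand$matches == best$matches && cand$ov > best$ov)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(NA_character_)
  }
  off <- best$off
  ov <- best$ov
  cons_ov <- character(ov)
  for (k in seq_len(ov)) {
    ca <- a[off + k]
    cb <- b[k]
    cons_ov[k] <- if (ca == cb || q1[off + k] >= q2[k]) ca else cb
  }
  paste0(
    substr(seq1, 1, off),
    paste(cons_ov, collapse = ""),
    if (n2 > ov) substr(f2, ov + 1, n2) else ""
  )
}

# Best ungapped match of a germline segment against a read, allowing the
# segment to be exonucleolytically clipped at one end: `clip = "3p"` scores
# runs anchored at the 5' side of the overlap (V segments, clipped 3'),
# `clip = "5p"` runs anchored at the 3' side (J segments, clipped 5').
# Among runs of length >= min_len with identity >= min_ident the one with
# the most matching bases wins (ties: higher identity, then smaller offset).
# Returns list(offset (0-based segment start in read, may be negative),
# seg_from, seg_to (1-based matched segment range), matches, identity).
best_ungapped_match <- function(read_chars, seg_chars, min_len, min_ident,
                                clip = c("3p", "5p")) {
  clip <- match.arg(clip)
  n <- length(read_chars)
  m <- length(seg_chars)
  best <- NULL
  for (off in (-(m - min_len)):(n - min_len)) {
    lo_r <- max(1L, off + 1L)
    hi_r <- min(n, off + m)
    ov <- hi_r - lo_r + 1L
    if (ov < min_len) next
    lo_s <- lo_r - off
    eq <- read_chars[lo_r:hi_r] == seg_chars[lo_s:(lo_s + ov - 1L)]
    if (clip == "5p") eq <- rev(eq)
    cum <- cumsum(eq)
    lens <- seq_len(ov)
    ident <- cum / lens
    valid <- which(lens >= min_len & ident >= min_ident)
    if (length(valid) == 0) next
    l <- valid[order(-cum[valid], -ident[valid])][1]
    cand <- list(
      offset = off,
      matches = cum[l], identity = ident[l],
      seg_from = if (clip == "3p") lo_s else lo_s + ov - l,
      seg_to = if (clip == "3p") lo_s + l - 1L else lo_s + ov - 1L
    )
    if (is.null(best) || cand$matches > best$matches ||
      (cand$matches == best$matches && cand$identity > best$identity)) {
      best <- cand
    }
  }
  best
}

#' Assign V and J segments to a joined read
#'
#' The V call is the best ungapped match of a V segment's 3'-clipped terminal
#' window over at least `min_len` nt at identity `min_ident` or better,
#' scored by matching bases (the J call analogously with a 5'-clipped
#' window); the conserved anchor codons are mapped through the match and must
#' lie inside it. Ties are broken by higher identity, then the
#' lexicographically smaller name. Rejection (no qualifying V or J, or an
#' anchor falling outside the read) is a value, not an error.
#'
#' @param joined Joined consensus sequence.
#' @param registry Germline registry.
#' @param min_ident Minimum identity (default 0.9).
#' @param min_len Minimum match length (default 15).
#' @return A one-row tibble with `v_name`, `j_name`, `v_anchor`, `j_anchor`
#'   (0-based offsets of the anchor codons in `joined`), or `NULL` on
#'   rejection.
#' @export
assign_v_j <- function(joined, registry, min_ident = 0.9, min_len = 15L) {
  read_chars <- strsplit(joined, "")[[1]]
  pick <- function(kind, clip) {
    segs <- registry[registry$kind == kind, ]
    segs <- segs[order(segs$name), ]
    best <- NULL
    for (i in seq_len(nrow(segs))) {
      m <- best_ungapped_match(
        read_chars, strsplit(segs$sequence[i], "")[[1]],
        min_len, min_ident,
        clip = clip
      )
      if (is.null(m)) next
      # the anchor codon must lie inside the matched part of the segment
      anchor <- segs$anchor_offset[i]
      if (anchor + 1L < m$seg_from || anchor + 3L > m$seg_to) next
      if (is.null(best) || m$matches > best$matches ||
        (m$matches == best$matches && m$identity > best$identity)) {
        best <- c(m, list(name = segs$name[i], anchor = anchor))
      }
    }
    best
  }
  v <- pick("V", clip = "3p")
  j <- pick("J", clip = "5p")
  if (is.null(v) || is.null(j)) {
    return(NULL)
  }
  v_anchor <- v$offset + v$anchor
  j_anchor <- j$offset + j$anchor
  n <- length(read_chars)
  if (v_anchor < 0 || v_anchor + 3 > n || j_anchor < 0 || j_anchor + 3 > n ||
    j_anchor <= v_anchor) {
    return(NULL)
  }
  tibble(
    v_name = v$name, j_name = j$name,
    v_anchor = as.integer(v_anchor), j_anchor = as.integer(j_anchor)
  )
}

#' Cluster assigned reads into clonotypes
#'
#' One clonotype per unique (V, J, CDR3 nucleotide sequence) key;
#' `read_count` is the number of supporting reads and `frequency` the
#' fraction of all assigned reads.
#'
#' @param assigned Tibble with columns `v_name`, `j_name`, `cdr3_nt` (one row
#'   per read; an optional `n` column gives per-row read multiplicities).
#' @return Clonotype tibble sorted by decreasing `read_count`.
#' @export
cluster_clonotypes <- function(assigned) {
  if (nrow(assigned) == 0) {
    return(tibble(
      v_name = character(), j_name = character(), cdr3_nt = character(),
      read_count = integer(), frequency = numeric()
    ))
  }
  if (!"n" %in% names(assigned)) assigned$n <- 1L
  out <- assigned %>%
    dplyr::group_by(.data$v_name, .data$j_name, .data$cdr3_nt) %>%
    dplyr::summarise(read_count = sum(.data$n), .groups = "drop")
  out$frequency <- out$read_count / sum(out$read_count)
  dplyr::arrange(
    out, dplyr::desc(.data$read_count),
    .data$v_name, .data$j_name, .data$cdr3_nt
  )
}

#' Merge 1-bp-neighbour clonotypes
#'
#' A clonotype is absorbed into a single-substitution neighbour (same V and J,
#' equal CDR3 length, Hamming distance 1) when that neighbour is at least
#' `fold_threshold`-fold more frequent; the recipient is the most abundant
#' qualifying neighbour. Clonotypes are processed in ascending abundance and
#' eligibility is recomputed as counts grow, so the total read count is
#' conserved exactly.
#'
#' @param table Clonotype tibble from [cluster_clonotypes()].
#' @param fold_threshold Minimum recipient/donor count ratio (default 20).
#' @return The merged clonotype tibble (frequencies recomputed over the same
#'   total).
#' @export
merge_neighbor_clonotypes <- function(table, fold_threshold = 20) {
  n <- nrow(table)
  if (n < 2) {
    return(table)
  }
  counts <- as.numeric(table$read_count)
  total <- sum(counts)
  key <- paste(table$v_name, table$j_name, nchar(table$cdr3_nt))
  alive <- rep(TRUE, n)
  chars <- strsplit(table$cdr3_nt, "")
  hamming1 <- function(i, j) {
    d <- 0L
    a <- chars[[i]]
    b <- chars[[j]]
    for (k in seq_along(a)) {
      if (a[k] != b[k]) {
        d <- d + 1L
        if (d > 1L) {
          return(FALSE)
        }
      }
    }
    d == 1L
  }
  repeat {
    ord <- order(counts + ifelse(alive, 0, Inf)) # ascending, alive first
    merged_any <- FALSE
    for (i in ord) {
      if (!alive[i]) next
      cand <- which(alive & key == key[i] &
        counts >= fold_threshold * counts[i])
      cand <- cand[cand != i]
      if (length(cand) == 0) next
      cand <- cand[vapply(cand, hamming1, logical(1), i = i)]
      if (length(cand) == 0) next
      recipient <- cand[which.max(counts[cand])]
      counts[recipient] <- counts[recipient] + counts[i]
      alive[i] <- FALSE
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  out <- table[alive, ]
  out$read_count <- as.integer(counts[alive])
  out$frequency <- out$read_count / total
  dplyr::arrange(
    out, dplyr::desc(.data$read_count),
    .data$v_name, .data$j_name, .data$cdr3_nt
  )
}

#' Apply the clonotype frequency cutoff
#'
#' Removes rows with frequency strictly below `cutoff` (the standard 0.001%
#' default); surviving rows keep their original frequencies (the denominator
#' remains the pre-cutoff assigned-read total).
#'
#' @param table Clonotype tibble with a `frequency` column.
#' @param cutoff Frequency cutoff as a fraction (default 1e-5).
#' @return The filtered tibble.
#' @export
apply_frequency_cutoff <- function(table, cutoff = 1e-5) {
  table[table$frequency >= cutoff, ]
}

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) {
    return(0L)
  }
  ca <- strsplit(substr(a, 1, n), "")[[1]]
  cb <- strsplit(substr(b, 1, n), "")[[1]]
  neq <- which(ca != cb)
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Decompose a clonotype's CDR3 into its VDJ architecture
#'
#' The matched V prefix is the longest common prefix of the CDR3 with the V
#' germline from its anchor codon (J suffix analogously); the remaining
#' junction is searched for the longest contiguous exact substring of any
#' germline D. A D of at least `min_d_match` nt assigns `d_name` and splits
#' the junction into N1 | kept D | N2; ties prefer the longer match, then the
#' D earlier in genomic order (D1), then the leftmost placement, and are
#' flagged `d_ambiguous`. Functionality is in-frame (CDR3 length divisible by
#' 3) and stop-free in the reading frame anchored at the V cysteine codon.
#'
#' @param cdr3_nt CDR3 nucleotide sequence (anchor codon to anchor codon).
#' @param v_name,j_name Assigned segment names.
#' @param registry Germline registry.
#' @param min_d_match Minimum D match length (default 5).
#' @return One-row tibble: `d_name`, `v_trunc`, `d5_trunc`, `d3_trunc`,
#'   `j_trunc`, `n1_seq`, `n2_seq`, `n1_len`, `n2_len`, `cdr3_len`,
#'   `functional`, `d_ambiguous`.
#' @export
decompose_architecture <- function(cdr3_nt, v_name, j_name, registry,
                                   min_d_match = 5L) {
  v <- registry[registry$name == v_name, ]
  j <- registry[registry$name == j_name, ]
  if (nrow(v) != 1 || nrow(j) != 1) abort("unknown V or J segment name")
  v_germ <- substr(v$sequence, v$anchor_offset + 1L, nchar(v$sequence))
  j_germ <- substr(j$sequence, 1, j$anchor_offset + 3L)
  n <- nchar(cdr3_nt)
  if (n < 6) abort("CDR3 shorter than the two anchor codons")

  # matched V prefix / J suffix; a sequencing error inside an anchor codon can
  # shorten these below the codon itself, which is tolerated (the junction
  # simply grows), not an error
  v_match <- lcp_len(cdr3_nt, v_germ)
  v_trunc <- nchar(v_germ) - v_match
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  j_match <- lcp_len(rev_str(cdr3_nt), rev_str(j_germ))
  j_trunc <- nchar(j_germ) - j_match
  # V and J matches must not overlap inside the CDR3
  if (v_match + j_match > n) {
    shrink <- v_match + j_match - n
    j_match <- j_match - shrink
    j_trunc <- j_trunc + shrink
  }
  junction <- substr(cdr3_nt, v_match + 1L, n - j_match)

  ds <- registry[registry$kind == "D", ]
  ds <- ds[order(ds$name), ] # genomic order preference: D1 before D2
  best <- NULL
  n_best_sites <- 0L
  jl <- nchar(junction)
  if (jl >= min_d_match) {
    for (di in seq_len(nrow(ds))) {
      dseq <- ds$sequence[di]
      dlen <- nchar(dseq)
      for (start in seq_len(jl - min_d_match + 1L)) {
        # longest match of junction[start..] as substring of D
        max_here <- min(jl - start + 1L, dlen)
        len <- 0L
        pos_in_d <- NA_integer_
        for (l in seq(max_here, min_d_match)) {
          hit <- regexpr(substr(junction, start, start + l - 1L), dseq,
            fixed = TRUE
          )
          if (hit > 0) {
            len <- l
            pos_in_d <- as.integer(hit)
            break
          }
        }
        if (len < min_d_match) next
        if (!is.null(best) && len == best$len &&
          (di != best$di || start != best$start)) {
          n_best_sites <- n_best_sites + 1L
        }
        if (is.null(best) || len > best$len) {
          best <- list(di = di, start = start, len = len, pos_in_d = pos_in_d)
          n_best_sites <- 1L
        }
      }
    }
  }

  functional <- is_functional_cdr3(cdr3_nt)
  if (is.null(best)) {
    return(tibble(
      d_name = NA_character_, v_trunc = as.integer(v_trunc),
      d5_trunc = NA_integer_, d3_trunc = NA_integer_,
      j_trunc = as.integer(j_trunc),
      n1_seq = junction, n2_seq = NA_character_,
      n1_len = nchar(junction), n2_len = NA_integer_,
      cdr3_len = as.integer(n), functional = functional,
      d_ambiguous = FALSE
    ))
  }
  d <- ds[best$di, ]
  d5_trunc <- best$pos_in_d - 1L
  d3_trunc <- nchar(d$sequence) - (best$pos_in_d - 1L) - best$len
  tibble(
    d_name = d$name, v_trunc = as.integer(v_trunc),
    d5_trunc = as.integer(d5_trunc), d3_trunc = as.integer(d3_trunc),
    j_trunc = as.integer(j_trunc),
    n1_seq = substr(junction, 1, best$start - 1L),
    n2_seq = substr(junction, best$start + best$len, jl),
    n1_len = best$start - 1L,
    n2_len = jl - (best$start + best$len - 1L),
    cdr3_len = as.integer(n), functional = functional,
    d_ambiguous = n_best_sites > 1L
  )
}

#' Run the full clonotype pipeline on paired reads
#'
#' Joins read pairs, assigns V/J, extracts CDR3s, clusters into clonotypes,
#' merges 1-bp/20-fold neighbours, applies the frequency cutoff and
#' decomposes each surviving clonotype's architecture. Identical read pairs
#' are processed once (the assignment is a pure function of the joined
#' sequence), so deep samples of few clonotypes stay fast. Deterministic:
#' the same input yields byte-identical tables.
#'
#' @param pairs Read-pair tibble from [read_fastq_pairs()] or
#'   [simulate_reads()].
#' @param registry Germline registry.
#' @param config A [vdj_config()] list.
#' @param sample_name Sample label recorded on every row.
#' @return Clonotype tibble with architecture columns (see
#'   [decompose_architecture()]).
#' @export
profile_repertoire <- function(pairs, registry = load_germline_registry(),
                               config = vdj_config(), sample_name = "sample1") {
  uniq <- pairs %>%
    dplyr::count(.data$seq1, .data$seq2, name = "n")
  qual_of <- function(s) rep(37L, nchar(s))
  joined <- vapply(seq_len(nrow(uniq)), function(i) {
    join_read_pair(
      uniq$seq1[i], uniq$seq2[i],
      qual_of(uniq$seq1[i]), qual_of(uniq$seq2[i]),
      min_overlap = config$join_min_overlap,
      max_mismatch_frac = config$join_max_mismatch_frac
    )
  }, character(1))
  uniq$joined <- joined
  uniq <- uniq[!is.na(uniq$joined), ]
  assigned <- purrr::map(seq_len(nrow(uniq)), function(i) {
    a <- assign_v_j(
      uniq$joined[i], registry,
      min_ident = config$assign_min_ident, min_len = config$assign_min_len
    )
    if (is.null(a)) {
      return(NULL)
    }
    a$cdr3_nt <- substr(uniq$joined[i], a$v_anchor + 1L, a$j_anchor + 3L)
    a$n <- uniq$n[i]
    a
  })
  assigned <- dplyr::bind_rows(assigned)
  if (nrow(assigned) == 0) {
    tbl <- cluster_clonotypes(tibble(
      v_name = character(), j_name = character(), cdr3_nt = character()
    ))
  } else {
    tbl <- cluster_clonotypes(
      assigned[, c("v_name", "j_name", "cdr3_nt", "n")]
    )
  }
  if (config$cutoff_before_merge) {
    tbl <- apply_frequency_cutoff(tbl, config$clonotype_frequency_cutoff)
    tbl <- merge_neighbor_clonotypes(tbl, config$merge_fold_threshold)
  } else {
    tbl <- merge_neighbor_clonotypes(tbl, config$merge_fold_threshold)
    tbl <- apply_frequency_cutoff(tbl, config$clonotype_frequency_cutoff)
  }
  if (nrow(tbl) == 0) {
    return(dplyr::bind_cols(
      tibble(sample = character()), tbl[, 0],
      decompose_architecture(
        "TGTTTC", registry$name[registry$kind == "V"][1],
        registry$name[registry$kind == "J"][1], registry
      )[0, ]
    ))
  }
  arch <- purrr::map(seq_len(nrow(tbl)), function(i) {
    decompose_architecture(
      tbl$cdr3_nt[i], tbl$v_name[i], tbl$j_name[i], registry,
      min_d_match = config$min_d_match
    )
  })
  out <- dplyr::bind_cols(tbl, dplyr::bind_rows(arch))
  out$sample <- sample_name
  dplyr::relocate(out, "sample")
}
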