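#' Repertoire simulation parameters
#'
#' Knobs of the seeded TCR-beta repertoire generator. Truncation lengths are
#' geometric (given mean), N-region lengths Poisson (applied independently to
#' N1 and N2, bases i.i.d. uniform), clone sizes follow a rank-based discrete
#' power law (Zipf, exponent `clone_size_shape`) truncated at `n_clonotypes`.
#' `p_functional` (optional) rejection-samples junctions toward a target
#' functional fraction, emulating thymic selection pressure on the
#' functional/non-functional ratio; `NA` disables it.
#'
#' @param n_clonotypes Number of distinct rearrangements to draw.
#' @param p_d2 Probability of using the D2 over the D1 segment.
#' @param v_trunc_mean,j_trunc_mean,d5_trunc_mean,d3_trunc_mean Mean
#'   exonucleolytic truncations (nt) at the V 3', J 5', D 5' and D 3' ends.
#' @param n_len_mean Mean N-region length (nt, per junction).
#' @param clone_size_shape Zipf exponent of the clone-abundance law.
#' @param read_depth Total read pairs to simulate.
#' @param error_rate Per-base substitution probability in reads.
#' @param p_functional Target functional clonotype fraction, or `NA`.
#' @param seed Integer RNG seed.
#' @return A named list of class `repertoire_sim_params`.
#' @export
sim_params <- function(n_clonotypes = 2000, p_d2 = 0.4,
                       v_trunc_mean = 2, j_trunc_mean = 2,
                       d5_trunc_mean = 1.5, d3_trunc_mean = 1.5,
                       n_len_mean = 3, clone_size_shape = 1,
                       read_depth = 20000, error_rate = 0.002,
                       p_functional = NA, seed = 1L) {
  p <- list(
    n_clonotypes = as.integer(n_clonotypes), p_d2 = p_d2,
    v_trunc_mean = v_trunc_mean, j_trunc_mean = j_trunc_mean,
    d5_trunc_mean = d5_trunc_mean, d3_trunc_mean = d3_trunc_mean,
    n_len_mean = n_len_mean, clone_size_shape = clone_size_shape,
    read_depth = as.integer(read_depth), error_rate = error_rate,
    p_functional = p_functional, seed = as.integer(seed)
  )
  if (p$p_d2 < 0 || p$p_d2 > 1) abort("p_d2 must be in [0, 1]")
  means <- c(
    p$v_trunc_mean, p$j_trunc_mean, p$d5_trunc_mean, p$d3_trunc_mean,
    p$n_len_mean
  )
  if (any(means < 0)) abort("all distribution means must be >= 0")
  if (p$error_rate < 0 || p$error_rate > 0.1) {
    abort("error_rate must be in [0, 0.1]")
  }
  if (p$n_clonotypes < 1) abort("n_clonotypes must be >= 1")
  structure(p, class = c("repertoire_sim_params", "list"))
}

rgeom_mean <- function(n, mean) {
  if (mean <= 0) {
    return(integer(n))
  }
  stats::rgeom(n, prob = 1 / (1 + mean))
}

random_bases <- function(lengths) {
  total <- sum(lengths)
  bases <- sample(DNA_BASES, total, replace = TRUE)
  out <- character(length(lengths))
  idx <- c(0, cumsum(lengths))
  for (i in seq_along(lengths)) {
    out[i] <- if (lengths[i] == 0) "" else {
      paste(bases[(idx[i] + 1):idx[i + 1]], collapse = "")
    }
  }
  out
}

# In-frame and stop-free in the reading frame anchored at the V cysteine codon.
is_functional_cdr3 <- function(cdr3) {
  vapply(cdr3, function(s) {
    n <- nchar(s)
    if (n %% 3 != 0) {
      return(FALSE)
    }
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    !any(codons %in% c("TAA", "TAG", "TGA"))
  }, logical(1), USE.NAMES = FALSE)
}

#' Simulate a TCR-beta repertoire with known architecture
#'
#' Draws `n_clonotypes` rearrangements from the registry with seeded,
#' parameterised junctional architecture and returns the truth table: one row
#' per unique clonotype with its full decomposition and Zipf abundance.
#' Truncations are capped so that the kept segment parts (and the V/J anchor
#' codons) survive. Clonotypes whose kept D part is shorter than `min_d_match`
#' are reported with `d_name = NA` and the whole junction as `n1_seq`,
#' mirroring what any D-assignment downstream can recover.
#'
#' @param params A [sim_params()] object.
#' @param registry A germline registry (see [load_germline_registry()]).
#' @param min_d_match Minimum recoverable D length (default 5 nt).
#' @return A truth tibble with clonotype, architecture and `frequency`
#'   columns; attribute `"params"` carries `params`.
#' @export
simulate_repertoire <- function(params, registry = load_germline_registry(),
                                min_d_match = 5L) {
  stopifnot(inherits(params, "repertoire_sim_params"))
  registry <- validate_registry(registry)
  vs <- registry[registry$kind == "V", ]
  ds <- registry[registry$kind == "D", ]
  js <- registry[registry$kind == "J", ]
  if (nrow(ds) != 2) abort("registry must carry exactly two D segments (D1, D2)")
  d1 <- ds[grepl("D1", ds$name), ]
  d2 <- ds[grepl("D2", ds$name), ]
  if (nrow(d1) != 1 || nrow(d2) != 1) abort("D segments must be named *D1* and *D2*")

  v_caps <- nchar(vs$sequence) - vs$anchor_offset - 3L
  j_caps <- js$anchor_offset
  if (params$v_trunc_mean > min(v_caps)) {
    abort("v_trunc_mean exceeds the V contribution available beyond the anchor")
  }
  if (params$j_trunc_mean > min(j_caps)) {
    abort("j_trunc_mean exceeds the J head length")
  }
  if (params$d5_trunc_mean > min(nchar(ds$sequence)) ||
    params$d3_trunc_mean > min(nchar(ds$sequence))) {
    abort("D truncation mean exceeds the D segment length")
  }

  n <- params$n_clonotypes
  v_seq <- vs$sequence
  v_anchor <- vs$anchor_offset
  j_seq <- js$sequence
  j_anchor <- js$anchor_offset
  d_name_by <- c(d1$name, d2$name)
  d_seq_by <- c(d1$sequence, d2$sequence)
  with_seed(params$seed, {
    vi <- sample.int(nrow(vs), n, replace = TRUE)
    ji <- sample.int(nrow(js), n, replace = TRUE)
    use_d2 <- stats::runif(n) < params$p_d2

    draw_junction <- function(k) {
      di <- if (use_d2[k]) 2L else 1L
      dseq <- d_seq_by[di]
      dlen <- nchar(dseq)
      v_trunc <- min(rgeom_mean(1, params$v_trunc_mean), v_caps[vi[k]])
      j_trunc <- min(rgeom_mean(1, params$j_trunc_mean), j_caps[ji[k]])
      d5 <- min(rgeom_mean(1, params$d5_trunc_mean), dlen)
      d3 <- min(rgeom_mean(1, params$d3_trunc_mean), dlen - d5)
      n1 <- random_bases(stats::rpois(1, params$n_len_mean))
      n2 <- random_bases(stats::rpois(1, params$n_len_mean))
      kept_v <- substr(
        v_seq[vi[k]], v_anchor[vi[k]] + 1L, nchar(v_seq[vi[k]]) - v_trunc
      )
      kept_d <- if (d5 + d3 >= dlen) "" else substr(dseq, d5 + 1L, dlen - d3)
      kept_j <- substr(j_seq[ji[k]], j_trunc + 1L, j_anchor[ji[k]] + 3L)
      cdr3 <- paste0(kept_v, n1, kept_d, n2, kept_j)
      list(
        d_used = d_name_by[di], v_trunc = v_trunc, j_trunc = j_trunc,
        d5_trunc = d5, d3_trunc = d3, n1 = n1, n2 = n2,
        kept_d_len = nchar(kept_d), cdr3 = cdr3,
        functional = is_functional_cdr3(cdr3)
      )
    }

    rows <- vector("list", n)
    for (k in seq_len(n)) {
      jn <- draw_junction(k)
      if (!is.na(params$p_functional)) {
        want <- stats::runif(1) < params$p_functional
        tries <- 0
        while (jn$functional != want && tries < 60) {
          jn <- draw_junction(k)
          tries <- tries + 1
        }
      }
      rows[[k]] <- jn
    }

    weight <- (seq_len(n))^(-params$clone_size_shape)
    truth <- tibble(
      clonotype_id = seq_len(n),
      v_name = vs$name[vi],
      d_used = purrr::map_chr(rows, "d_used"),
      j_name = js$name[ji],
      v_trunc = purrr::map_int(rows, ~ as.integer(.x$v_trunc)),
      d5_trunc = purrr::map_int(rows, ~ as.integer(.x$d5_trunc)),
      d3_trunc = purrr::map_int(rows, ~ as.integer(.x$d3_trunc)),
      j_trunc = purrr::map_int(rows, ~ as.integer(.x$j_trunc)),
      n1_seq = purrr::map_chr(rows, "n1"),
      n2_seq = purrr::map_chr(rows, "n2"),
      kept_d_len = purrr::map_int(rows, ~ as.integer(.x$kept_d_len)),
      cdr3_nt = purrr::map_chr(rows, "cdr3"),
      functional = purrr::map_lgl(rows, "functional"),
      weight = weight
    )
  })

  # truth-normalise: a kept D below min_d_match is invisible downstream
  invisible_d <- truth$kept_d_len < min_d_match
  truth$d_name <- ifelse(invisible_d, NA_character_, truth$d_used)
  full_junction <- paste0(
    truth$n1_seq,
    ifelse(invisible_d & truth$kept_d_len > 0,
      substr_kept_d(truth, registry), ""
    ),
    truth$n2_seq
  )
  truth$n1_seq <- ifelse(invisible_d, full_junction, truth$n1_seq)
  truth$n2_seq <- ifelse(invisible_d, NA_character_, truth$n2_seq)
  truth$d5_trunc <- ifelse(invisible_d, NA_integer_, truth$d5_trunc)
  truth$d3_trunc <- ifelse(invisible_d, NA_integer_, truth$d3_trunc)

  truth$cdr3_len <- nchar(truth$cdr3_nt)
  truth$n1_len <- nchar(truth$n1_seq)
  truth$n2_len <- ifelse(is.na(truth$n2_seq), NA_integer_, nchar(truth$n2_seq))

  # collapse clonotype-key duplicates (same V, J, CDR3), summing abundance
  truth <- truth %>%
    dplyr::group_by(.data$v_name, .data$j_name, .data$cdr3_nt) %>%
    dplyr::mutate(weight = sum(.data$weight)) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$clonotype_id)
  truth$frequency <- truth$weight / sum(truth$weight)
  attr(truth, "params") <- params
  truth
}

# kept-D substring for rows whose D is below the reporting threshold
substr_kept_d <- function(truth, registry) {
  dseq <- stats::setNames(
    registry$sequence[registry$kind == "D"],
    registry$name[registry$kind == "D"]
  )
  vapply(seq_len(nrow(truth)), function(i) {
    s <- dseq[[truth$d_used[i]]]
    if (truth$kept_d_len[i] == 0) "" else {
      substr(s, truth$d5_trunc[i] + 1L, nchar(s) - truth$d3_trunc[i])
    }
  }, character(1))
}

#' Simulate paired-end reads from a repertoire truth table
#'
#' Each clonotype's amplicon is its full rearrangement (germline V head +
#' CDR3 + germline J tail, the V head and J tail doubling as the fixed primer
#' landing sequences); read counts are multinomial over clonotype frequencies,
#' substitution errors i.i.d. at `error_rate`, R2 is the reverse-complement
#' strand. Deterministic given the parameter seed.
#'
#' @param truth Truth table from [simulate_repertoire()].
#' @param params The same [sim_params()] object.
#' @param registry The germline registry used for simulation.
#' @param read_length Read length of each mate (default 150).
#' @param min_overlap Minimum mate overlap the amplicons must allow.
#' @return A read-pair tibble as returned by [read_fastq_pairs()], with
#'   attribute `"read_counts"` (reads per truth row).
#' @export
simulate_reads <- function(truth, params, registry = load_germline_registry(),
                           read_length = 150L, min_overlap = 10L) {
  stopifnot(inherits(params, "repertoire_sim_params"))
  vs <- registry[registry$kind == "V", ]
  js <- registry[registry$kind == "J", ]
  v_head <- stats::setNames(
    substr(vs$sequence, 1, vs$anchor_offset), vs$name
  )
  j_tail <- stats::setNames(
    substr(js$sequence, js$anchor_offset + 4L, nchar(js$sequence)), js$name
  )
  amplicon <- paste0(
    v_head[truth$v_name], truth$cdr3_nt, j_tail[truth$j_name]
  )
  too_long <- nchar(amplicon) > 2L * read_length - min_overlap
  if (any(too_long)) {
    abort(sprintf(
      "amplicon %d longer than 2 x read_length - min_overlap",
      which(too_long)[1]
    ))
  }
  with_seed(params$seed + 1L, {
    counts <- if (params$read_depth == 0) {
      integer(nrow(truth))
    } else {
      as.integer(stats::rmultinom(1, params$read_depth, truth$frequency))
    }
    idx <- rep(seq_len(nrow(truth)), counts)
    amp <- amplicon[idx]
    alen <- nchar(amp)
    r1 <- substr(amp, 1, pmin(read_length, alen))
    r2 <- revcomp(substr(amp, pmax(1, alen - read_length + 1L), alen))
    if (params$error_rate > 0 && length(amp) > 0) {
      r1 <- add_substitution_errors(r1, params$error_rate)
      r2 <- add_substitution_errors(r2, params$error_rate)
    }
    qual1 <- lapply(nchar(r1), function(n) rep(37L, n))
    qual2 <- lapply(nchar(r2), function(n) rep(37L, n))
    pairs <- tibble(
      read_id = sprintf(
        "cl%d_r%d", idx,
        stats::ave(idx, idx, FUN = seq_along)
      ),
      seq1 = r1, qual1 = qual1, seq2 = r2, qual2 = qual2
    )
  })
  attr(pairs, "read_counts") <- counts
  pairs
}

add_substitution_errors <- function(reads, rate) {
  total <- sum(nchar(reads))
  n_err <- stats::rbinom(1, total, rate)
  if (n_err == 0) {
    return(reads)
  }
  pos <- sort(sample.int(total, n_err))
  offsets <- c(0, cumsum(nchar(reads)))
  read_of <- findInterval(pos, offsets, left.open = TRUE)
  within <- pos - offsets[read_of]
  for (k in seq_along(pos)) {
    i <- read_of[k]
    j <- within[k]
    old <- substr(reads[i], j, j)
    new <- sample(setdiff(DNA_BASES, old), 1)
    substr(reads[i], j, j) <- new
  }
  reads
}

#' Genome simulation parameters
#'
#' @param length Genome length in nt (>= 1000).
#' @param gc GC fraction of the i.i.d. background.
#' @param n_planted_rss,n_planted_runx1_overlap,n_planted_lone_heptamer
#'   Numbers of planted consensus sites of each class (see
#'   [rss_site_templates()]; the RUNX1-overlap class is the
#'   heptamer-within-RSS-module composite).
#' @param seed Integer RNG seed.
#' @return A named list of class `genome_sim_params`.
#' @export
genome_sim_params <- function(length = 50000L, gc = 0.41,
                              n_planted_rss = 0L,
                              n_planted_runx1_overlap = 0L,
                              n_planted_lone_heptamer = 0L, seed = 1L) {
  p <- list(
    length = as.integer(length), gc = gc,
    n_planted_rss = as.integer(n_planted_rss),
    n_planted_runx1_overlap = as.integer(n_planted_runx1_overlap),
    n_planted_lone_heptamer = as.integer(n_planted_lone_heptamer),
    seed = as.integer(seed)
  )
  if (p$length < 1000) abort("genome length must be >= 1000")
  if (p$gc <= 0 || p$gc >= 1) abort("gc must be in (0, 1)")
  if (any(unlist(p[3:5]) < 0)) abort("planted counts must be >= 0")
  structure(p, class = c("genome_sim_params", "list"))
}

random_genome <- function(length, gc) {
  paste(
    sample(DNA_BASES, length,
      replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ),
    collapse = ""
  )
}

# place n non-overlapping intervals of widths `w` inside [margin, L - margin)
place_nonoverlapping <- function(n, w, L, taken, margin = 50L,
                                 max_tries = 10000L) {
  starts <- integer(0)
  widths <- integer(0)
  tries <- 0
  while (length(starts) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- sample.int(L - 2L * margin - max(w), 1) + margin
    cw <- w[length(starts) + 1L]
    ok <- all(interval_overlap(
      cand - 1L, cand + cw + 1L, taken$start, taken$end
    ) == 0)
    if (ok) {
      starts <- c(starts, cand)
      widths <- c(widths, cw)
      taken <- dplyr::bind_rows(taken, tibble(start = cand, end = cand + cw))
    }
  }
  if (length(starts) < n) {
    abort("cannot place requested planted sites without overlap")
  }
  list(starts = starts, taken = taken)
}

#' Simulate a genome with planted motif sites
#'
#' Background bases are i.i.d. at the given GC; consensus templates (full RSS,
#' RUNX1-overlapping heptamer inside an RSS module, lone heptamer) are planted
#' at non-overlapping recorded positions.
#'
#' @param params A [genome_sim_params()] object.
#' @param templates Named templates (default [rss_site_templates()]).
#' @param chrom Chromosome name of the simulated sequence.
#' @return List with `genome` (named character vector) and `truth` (tibble
#'   with `chrom`, `start`, `end`, `class`, `strand`, `runx1_start`).
#' @export
simulate_genome <- function(params, templates = rss_site_templates(),
                            chrom = "chrSim") {
  stopifnot(inherits(params, "genome_sim_params"))
  runx1_off <- attr(templates, "runx1_offset")
  plan <- c(
    rep("rss", params$n_planted_rss),
    rep("runx1_rss", params$n_planted_runx1_overlap),
    rep("lone_heptamer", params$n_planted_lone_heptamer)
  )
  with_seed(params$seed, {
    genome <- random_genome(params$length, params$gc)
    truth <- tibble(
      chrom = character(), start = integer(), end = integer(),
      class = character(), strand = character(), runx1_start = integer()
    )
    if (length(plan) > 0) {
      w <- nchar(templates[plan])
      placed <- place_nonoverlapping(
        length(plan), w, params$length,
        taken = tibble(start = integer(), end = integer())
      )
      for (i in seq_along(plan)) {
        s <- placed$starts[i]
        tpl <- templates[[plan[i]]]
        substr(genome, s + 1L, s + nchar(tpl)) <- tpl
        truth <- dplyr::bind_rows(truth, tibble(
          chrom = chrom, start = s, end = s + nchar(tpl),
          class = plan[i], strand = "+",
          runx1_start = if (is.na(runx1_off[[plan[i]]])) NA_integer_ else {
            s + runx1_off[[plan[i]]]
          }
        ))
      }
    }
  })
  genome_vec <- stats::setNames(genome, chrom)
  list(genome = genome_vec, truth = dplyr::arrange(truth, .data$start))
}

#' Simulate a deletion cohort with planted RUNX1 sites at the borders
#'
#' Draws non-overlapping deletions on the given genome and, for a planted
#' fraction, writes a RUNX1-overlapping heptamer template into the 67-bp end
#' region of one border at a controlled distance (RUNX1 first nucleotide to
#' the border). The default plants the RSS-module class; a `plan` tibble
#' (columns `class` in `runx1_rss`/`runx1_heptamer`/`runx1_only`, `fraction`,
#' `distance`) plants several classes in one cohort.
#'
#' @param genome Named character vector (single chromosome used).
#' @param n_deletions Number of deletions.
#' @param enriched_fraction Fraction of deletions that receive a planted site.
#' @param distance_law Constant distance in bp, or a function of `n` returning
#'   distances (4-25 bp supported by the region geometry).
#' @param seed Integer RNG seed.
#' @param plan Optional multi-class planting plan (overrides
#'   `enriched_fraction`/`distance_law`).
#' @param deletion_span Deletion length range (uniform draw).
#' @return List with `genome` (modified), `deletions` (chrom/start/end
#'   tibble) and `truth` (deletion_id, side, class, distance, runx1_start).
#' @export
simulate_deletion_cohort <- function(genome, n_deletions,
                                     enriched_fraction = 0,
                                     distance_law = 6, seed = 1L,
                                     plan = NULL,
                                     deletion_span = c(200L, 400L)) {
  chrom <- names(genome)[1]
  seq <- genome[[1]]
  L <- nchar(seq)
  if (is.null(plan)) {
    plan <- tibble(
      class = "runx1_rss", fraction = enriched_fraction,
      distance = list(distance_law)
    )
  } else if (!is.list(plan$distance)) {
    plan$distance <- as.list(plan$distance)
  }
  if (sum(plan$fraction) > 1 + 1e-9) abort("planted fractions exceed 1")
  templates <- rss_site_templates()
  runx1_off <- attr(templates, "runx1_offset")
  with_seed(seed, {
    widths <- sample(seq(deletion_span[1], deletion_span[2]), n_deletions,
      replace = TRUE
    )
    placed <- place_nonoverlapping(
      n_deletions, widths + 160L, L,
      taken = tibble(start = integer(), end = integer()),
      margin = 100L
    )
    starts <- sort(placed$starts) + 80L
    dels <- tibble(
      chrom = chrom, start = starts, end = starts + widths[order(placed$starts)]
    )
    # assign planted classes to deletions
    n_planted <- round(plan$fraction * n_deletions)
    class_vec <- rep(NA_character_, n_deletions)
    pool <- sample.int(n_deletions)
    at <- 1
    for (k in seq_len(nrow(plan))) {
      if (n_planted[k] == 0) next
      class_vec[pool[at:(at + n_planted[k] - 1)]] <- plan$class[k]
      at <- at + n_planted[k]
    }
    truth <- tibble(
      deletion_id = integer(), side = character(), class = character(),
      distance = integer(), runx1_start = integer()
    )
    for (i in seq_len(n_deletions)) {
      cls <- class_vec[i]
      if (is.na(cls)) next
      k <- match(cls, plan$class)
      dl <- plan$distance[[k]]
      d <- as.integer(if (is.function(dl)) dl(1) else dl)
      side <- sample(c("5prime", "3prime"), 1)
      tpl <- templates[[cls]]
      off <- runx1_off[[cls]]
      if (side == "5prime") {
        # reverse-complement orientation: RUNX1 at mirrored template offset,
        # bulk of the template points into the deleted span
        tpl_rc <- revcomp(tpl)
        off_rc <- nchar(tpl) - off - 11L
        border <- dels$start[i]
        tpl_start <- border + d - off_rc
        runx1_start <- border + d
        tpl_use <- tpl_rc
      } else {
        border <- dels$end[i]
        runx1_start <- border - d
        tpl_start <- runx1_start - off
        tpl_use <- tpl
      }
      if (tpl_start < 0 || tpl_start + nchar(tpl_use) > L) {
        abort("planted template does not fit the genome")
      }
      substr(seq, tpl_start + 1L, tpl_start + nchar(tpl_use)) <- tpl_use
      truth <- dplyr::bind_rows(truth, tibble(
        deletion_id = i, side = side, class = cls,
        distance = d, runx1_start = as.integer(runx1_start)
      ))
    }
  })
  genome[[1]] <- seq
  list(genome = genome, deletions = dels, truth = truth)
}
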