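#' Build 67-bp deletion-end regions
#'
#' Per deletion two regions of `inner_span + flank` bp: the 5' end
#' `[start - flank, start + inner_span)` and the 3' end
#' `[end - inner_span, end + flank)`, each carrying its border coordinate.
#' Regions running over a chromosome end are clipped and flagged.
#'
#' @param deletions Tibble with `chrom`, `start`, `end` (0-based half-open);
#'   every deletion must span at least `inner_span` bp.
#' @param genome Named character vector of chromosome sequences.
#' @param inner_span Bases taken inside the deletion (default 60).
#' @param flank Bases added beyond the border (default 7).
#' @return Region tibble with `chrom`, `start`, `end`, `sequence`, `role`
#'   (`deletion_5prime_end` / `deletion_3prime_end`), `border_position`,
#'   `deletion_id`, `clipped`.
#' @export
build_deletion_end_regions <- function(deletions, genome, inner_span = 60L,
                                       flank = 7L) {
  short <- which(deletions$end - deletions$start < inner_span)
  if (length(short) > 0) {
    abort(sprintf("deletion %d shorter than inner_span", short[1]))
  }
  five <- tibble(
    chrom = deletions$chrom,
    start = deletions$start - flank,
    end = deletions$start + inner_span,
    role = "deletion_5prime_end",
    border_position = deletions$start,
    deletion_id = seq_len(nrow(deletions))
  )
  three <- tibble(
    chrom = deletions$chrom,
    start = deletions$end - inner_span,
    end = deletions$end + flank,
    role = "deletion_3prime_end",
    border_position = deletions$end,
    deletion_id = seq_len(nrow(deletions))
  )
  regions <- dplyr::bind_rows(five, three) %>%
    dplyr::arrange(.data$deletion_id, .data$role)
  chrom_len <- stats::setNames(nchar(genome), names(genome))
  lo <- pmax(regions$start, 0L)
  hi <- pmin(regions$end, chrom_len[regions$chrom])
  regions$clipped <- lo != regions$start | hi != regions$end
  if (any(regions$clipped)) {
    warn(sprintf("%d deletion-end regions clipped at chromosome ends",
      sum(regions$clipped)))
  }
  regions$start <- as.integer(lo)
  regions$end <- as.integer(unname(hi))
  regions_with_sequence(regions, genome)
}

#' Extract and merge heptamer windows
#'
#' Each heptamer hit is expanded by `flank` nt on both sides and clipped to
#' its region; windows overlapping by at least one nucleotide are merged.
#' A window is `in_rss_module` if any contributing heptamer hit is the
#' heptamer of an RSS module hit in the same region (same start and strand).
#'
#' @param regions Region tibble (row order defines `region_id`).
#' @param hept_hits Heptamer hit tibble from [scan_regions()].
#' @param module_hits RSS module hit tibble from
#'   [scan_rss_modules_regions()] (may be empty).
#' @param flank Expansion in nt (default 7).
#' @return Window tibble: `region_id`, `start`, `end`, `n_hits`,
#'   `in_rss_module`, and a `hits` list-column of the contributing heptamer
#'   hit rows.
#' @export
extract_heptamer_windows <- function(regions, hept_hits,
                                     module_hits = NULL, flank = 7L) {
  if (nrow(hept_hits) == 0) {
    return(tibble(
      region_id = integer(), start = integer(), end = integer(),
      n_hits = integer(), in_rss_module = logical(), hits = list()
    ))
  }
  out <- hept_hits %>%
    dplyr::group_by(.data$region_id) %>%
    dplyr::group_map(function(h, key) {
      rid <- key$region_id
      rlen <- nchar(regions$sequence[rid])
      wstart <- pmax(h$start - flank, 0L)
      wend <- pmin(h$end + flank, rlen)
      merged <- merge_intervals(wstart, wend)
      in_mod <- logical(nrow(h))
      if (!is.null(module_hits) && nrow(module_hits) > 0) {
        mh <- module_hits[module_hits$region_id == rid, ]
        in_mod <- paste(h$start, h$strand) %in%
          paste(mh$hept_start, mh$strand)
      }
      tibble(
        region_id = rid,
        start = merged$start, end = merged$end,
        n_hits = lengths(merged$members),
        in_rss_module = purrr::map_lgl(merged$members, ~ any(in_mod[.x])),
        hits = purrr::map(merged$members, ~ h[.x, ])
      )
    }) %>%
    dplyr::bind_rows()
  dplyr::arrange(out, .data$region_id, .data$start)
}

#' Count RUNX1-positive heptamer windows
#'
#' A window is RUNX1-positive when some RUNX1 hit overlaps one of its
#' *contributing heptamer hits* (not merely the expanded window) by at least
#' `min_overlap` nt.
#'
#' @param windows Window tibble from [extract_heptamer_windows()].
#' @param runx1_hits RUNX1 hit tibble from [scan_regions()].
#' @param min_overlap Minimum heptamer-RUNX1 overlap in nt (default 4).
#' @return List with `n_windows`, `n_windows_with_runx1` and `detail` (the
#'   windows tibble plus a logical `runx1_positive` column).
#' @export
count_runx1_overlaps <- function(windows, runx1_hits, min_overlap = 4L) {
  positive <- vapply(seq_len(nrow(windows)), function(i) {
    rh <- runx1_hits[runx1_hits$region_id == windows$region_id[i], ]
    if (nrow(rh) == 0) {
      return(FALSE)
    }
    hh <- windows$hits[[i]]
    any(vapply(seq_len(nrow(hh)), function(k) {
      any(interval_overlap(
        rh$start, rh$end, hh$start[k], hh$end[k]
      ) >= min_overlap)
    }, logical(1)))
  }, logical(1))
  windows$runx1_positive <- positive
  list(
    n_windows = nrow(windows),
    n_windows_with_runx1 = sum(positive),
    detail = windows
  )
}

#' Foreground-vs-background motif enrichment
#'
#' Compares an observed count of positive units among `n_foreground`
#' foreground units against a background positive rate. The analytic method
#' reports `fold = observed / expected`, a continuity-corrected Z-score with
#' binomial (default) or Poisson standard deviation, and the exact binomial
#' tail probability (upper tail when observed exceeds expected, lower tail
#' otherwise). The resampling method draws seeded background samples and
#' reports the empirical Z and tail.
#'
#' @param observed Observed positive count in the foreground.
#' @param n_foreground Number of foreground units.
#' @param background_positive,background_total Background positive count and
#'   total unit count.
#' @param method `"analytic"` (default) or `"resampling"`.
#' @param variance `"binomial"` (default, SD `sqrt(n p (1-p))`) or
#'   `"poisson"` (SD `sqrt(expected)`; the large-background small-rate limit).
#' @param n_resamples,seed Resampling controls.
#' @return An object of class `vdj_enrichment`.
#' @export
#' @examples
#' motif_enrichment(15, 30, 76, 300, variance = "poisson")
motif_enrichment <- function(observed, n_foreground,
                             background_positive, background_total,
                             method = c("analytic", "resampling"),
                             variance = c("binomial", "poisson"),
                             n_resamples = 10000L, seed = 1L) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  if (background_total <= 0) abort("background_total must be positive")
  if (n_foreground <= 0) abort("n_foreground must be positive")
  p <- background_positive / background_total
  expected <- n_foreground * p
  degenerate <- p == 0
  fold <- if (degenerate) NA_real_ else observed / expected
  if (method == "analytic") {
    sd_bg <- if (variance == "binomial") {
      sqrt(n_foreground * p * (1 - p))
    } else {
      sqrt(expected)
    }
    z <- if (degenerate || sd_bg == 0) {
      if (observed > expected) Inf else 0
    } else {
      z_score(observed, expected, sd_bg)
    }
    p_tail <- if (observed >= expected) {
      binomial_upper_tail(observed, n_foreground, p)
    } else {
      binomial_lower_tail(observed, n_foreground, p)
    }
    res <- list(
      observed = observed, n_foreground = n_foreground,
      background_rate = p, expected = expected, fold = fold,
      z = z, p_binomial = p_tail, method = "analytic", variance = variance
    )
  } else {
    with_seed(seed, {
      draws <- stats::rbinom(n_resamples, n_foreground, p)
    })
    sd_emp <- stats::sd(draws)
    z <- if (sd_emp == 0) {
      if (observed > mean(draws)) Inf else 0
    } else {
      z_score(observed, mean(draws), sd_emp)
    }
    p_tail <- if (observed >= expected) {
      (sum(draws >= observed) + 1) / (n_resamples + 1)
    } else {
      (sum(draws <= observed) + 1) / (n_resamples + 1)
    }
    res <- list(
      observed = observed, n_foreground = n_foreground,
      background_rate = p, expected = expected, fold = fold,
      z = z, p_binomial = p_tail, method = "resampling",
      n_resamples = n_resamples, seed = seed
    )
  }
  structure(res, class = "vdj_enrichment")
}

#' @export
print.vdj_enrichment <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<vdj_enrichment> %d / %d foreground units positive\n",
      "  background rate %.4g  expected %.3g  fold %.3g  Z %.3g  P %.3g (%s)\n"
    ),
    x$observed, x$n_foreground, x$background_rate, x$expected,
    x$fold, x$z, x$p_binomial, x$method
  ))
  invisible(x)
}

#' Scan a background genome for heptamer windows and RSS modules
#'
#' Scans the whole provided genome once with the same matrices, thresholds
#' and window rules as the foreground and returns the background counts for
#' [motif_enrichment()]: merged heptamer windows, their RUNX1-positive
#' subset, and the same pair restricted to windows inside RSS modules.
#'
#' @param genome Named character vector.
#' @param models RSS models ([rss_models()]).
#' @param runx1_pwm RUNX1 matrix.
#' @param config A [vdj_config()] list (thresholds, flank, overlap).
#' @return List of counts: `n_hept_windows`, `n_hept_windows_runx1`,
#'   `n_rss_windows`, `n_rss_windows_runx1`, plus the per-chromosome window
#'   detail.
#' @export
scan_background_genome <- function(genome, models = rss_models(),
                                   runx1_pwm = default_runx1_pwm(),
                                   config = vdj_config()) {
  regions <- tibble(
    chrom = names(genome),
    start = 0L, end = nchar(unname(genome)),
    sequence = unname(genome),
    role = "background_window", border_position = NA_integer_
  )
  hept <- scan_hept_all(regions, models, config)
  modules <- scan_rss_modules_regions(
    regions, models,
    threshold_heptamer = config$similarity_threshold_heptamer,
    threshold_nonamer = config$similarity_threshold_nonamer
  )
  windows <- extract_heptamer_windows(
    regions, hept, modules,
    flank = config$window_flank
  )
  runx1 <- scan_regions(
    regions, runx1_pwm,
    threshold = config$similarity_threshold_runx1
  )
  counted <- count_runx1_overlaps(
    windows, runx1,
    min_overlap = config$min_runx1_heptamer_overlap
  )
  rss_detail <- counted$detail[counted$detail$in_rss_module, ]
  list(
    n_hept_windows = counted$n_windows,
    n_hept_windows_runx1 = counted$n_windows_with_runx1,
    n_rss_windows = nrow(rss_detail),
    n_rss_windows_runx1 = sum(rss_detail$runx1_positive),
    detail = counted$detail
  )
}

# heptamer hits of all distinct heptamer matrices used by the models,
# deduplicated by (region, start, strand)
scan_hept_all <- function(regions, models, config) {
  mats <- list()
  for (m in models) mats[[m$heptamer$name]] <- m$heptamer
  hits <- purrr::map(
    mats, ~ scan_regions(
      regions, .x,
      threshold = config$similarity_threshold_heptamer
    )
  )
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(out)
  }
  out <- out[order(out$region_id, out$start, out$strand, -out$score), ]
  out[!duplicated(paste(out$region_id, out$start, out$strand)), ]
}

#' Deletion-border RUNX1 enrichment analysis
#'
#' The full foreground pipeline over deletion-end regions: heptamer and RSS
#' module scanning, window extraction/merging, RUNX1 overlap counting, and
#' fold/Z/binomial enrichment against a background genome scanned with
#' identical settings. Two results are returned: all heptamer windows, and
#' the subset inside RSS modules.
#'
#' @param regions Deletion-end regions from [build_deletion_end_regions()].
#' @param background Background counts from [scan_background_genome()].
#' @param models,runx1_pwm,config As in [scan_background_genome()].
#' @param variance Variance model passed to [motif_enrichment()].
#' @return List with `windows` (per-window detail), `all_heptamers`
#'   (`vdj_enrichment`), `rss_modules` (`vdj_enrichment`).
#' @export
deletion_border_enrichment <- function(regions, background,
                                       models = rss_models(),
                                       runx1_pwm = default_runx1_pwm(),
                                       config = vdj_config(),
                                       variance = "binomial") {
  hept <- scan_hept_all(regions, models, config)
  modules <- scan_rss_modules_regions(
    regions, models,
    threshold_heptamer = config$similarity_threshold_heptamer,
    threshold_nonamer = config$similarity_threshold_nonamer
  )
  windows <- extract_heptamer_windows(
    regions, hept, modules,
    flank = config$window_flank
  )
  runx1 <- scan_regions(
    regions, runx1_pwm,
    threshold = config$similarity_threshold_runx1
  )
  counted <- count_runx1_overlaps(
    windows, runx1,
    min_overlap = config$min_runx1_heptamer_overlap
  )
  rss_detail <- counted$detail[counted$detail$in_rss_module, ]
  all_enr <- motif_enrichment(
    counted$n_windows_with_runx1, counted$n_windows,
    background$n_hept_windows_runx1, background$n_hept_windows,
    variance = variance
  )
  rss_enr <- if (nrow(rss_detail) > 0 && background$n_rss_windows > 0) {
    motif_enrichment(
      sum(rss_detail$runx1_positive), nrow(rss_detail),
      background$n_rss_windows_runx1, background$n_rss_windows,
      variance = variance
    )
  } else {
    NULL
  }
  list(
    windows = counted$detail, runx1_hits = runx1,
    hept_hits = hept, module_hits = modules,
    all_heptamers = all_enr, rss_modules = rss_enr
  )
}

#' Spatial classification of RUNX1 hits at deletion borders
#'
#' Every RUNX1 hit in a border region is assigned the most specific matching
#' category: `RUNX1_RSS` (>= `min_overlap` nt overlap with a heptamer hit
#' inside an RSS module), `RUNX1_heptamer` (same overlap with a lone heptamer
#' hit), `RUNX1_partial_heptamer_nonamer` (a GTG or CAC trinucleotide
#' immediately flanking the hit plus a same-strand nonamer hit at a spacer of
#' 12 or 19-25 nt from that flank), else `RUNX1_only`. The distance is the
#' unsigned offset of the hit's first (plus-strand) base from the region's
#' border coordinate; a signed variant (negative inside the deleted span) is
#' also reported.
#'
#' @param regions Regions with `border_position` (rows lacking it are dropped
#'   with a warning).
#' @param runx1_hits,hept_hits,module_hits Hit tibbles over the same regions.
#' @param nonamer_hits Nonamer hit tibble (for the partial category).
#' @param config A [vdj_config()] (overlap threshold, partial spacer classes).
#' @return Tibble of spatial records (`region_id`, `start`, `end`, `strand`,
#'   `category`, `distance_bp`, `distance_signed`); per-category medians via
#'   [spatial_medians()].
#' @export
spatial_classify <- function(regions, runx1_hits, hept_hits, module_hits,
                             nonamer_hits = NULL, config = vdj_config()) {
  no_border <- is.na(regions$border_position)
  if (any(no_border)) {
    warn(sprintf("%d regions without border_position excluded", sum(no_border)))
  }
  min_ov <- config$min_runx1_heptamer_overlap
  records <- purrr::map(seq_len(nrow(runx1_hits)), function(i) {
    rh <- runx1_hits[i, ]
    rid <- rh$region_id
    if (no_border[rid]) {
      return(NULL)
    }
    reg <- regions[rid, ]
    hh <- hept_hits[hept_hits$region_id == rid, ]
    mh <- module_hits[module_hits$region_id == rid, ]
    in_mod <- if (nrow(hh) > 0) {
      paste(hh$start, hh$strand) %in% paste(mh$hept_start, mh$strand)
    } else {
      logical(0)
    }
    ov <- if (nrow(hh) > 0) {
      interval_overlap(rh$start, rh$end, hh$start, hh$end)
    } else {
      integer(0)
    }
    category <- if (any(ov >= min_ov & in_mod)) {
      "RUNX1_RSS"
    } else if (any(ov >= min_ov)) {
      "RUNX1_heptamer"
    } else if (has_partial_heptamer_nonamer(
      reg, rh, nonamer_hits, config
    )) {
      "RUNX1_partial_heptamer_nonamer"
    } else {
      "RUNX1_only"
    }
    genomic_start <- reg$start + rh$start
    signed <- if (reg$role == "deletion_5prime_end") {
      genomic_start - reg$border_position
    } else {
      reg$border_position - genomic_start
    }
    tibble(
      region_id = rid, start = rh$start, end = rh$end, strand = rh$strand,
      score = rh$score, category = category,
      distance_bp = abs(genomic_start - reg$border_position),
      distance_signed = signed
    )
  })
  out <- dplyr::bind_rows(records)
  if (nrow(out) == 0) {
    return(tibble(
      region_id = integer(), start = integer(), end = integer(),
      strand = character(), score = numeric(), category = character(),
      distance_bp = integer(), distance_signed = integer()
    ))
  }
  out
}

# GTG or CAC immediately flanking the RUNX1 hit, plus a same-strand nonamer
# hit separated from that flank by a spacer inside a partial spacer class.
has_partial_heptamer_nonamer <- function(region, rh, nonamer_hits, config) {
  if (is.null(nonamer_hits)) {
    return(FALSE)
  }
  seq <- region$sequence
  rlen <- nchar(seq)
  nh <- nonamer_hits[
    nonamer_hits$region_id == rh$region_id & nonamer_hits$strand == rh$strand,
  ]
  if (nrow(nh) == 0) {
    return(FALSE)
  }
  in_class <- function(sp) {
    any(vapply(
      config$partial_spacer_classes,
      function(cl) sp >= cl[1] && sp <= cl[2], logical(1)
    ))
  }
  # right flank: trinucleotide at [end, end + 3), nonamer further right
  if (rh$end + 3 <= rlen) {
    tri <- substr(seq, rh$end + 1L, rh$end + 3L)
    if (tri %in% c("GTG", "CAC")) {
      spacers <- nh$start - (rh$end + 3L)
      if (any(vapply(spacers, in_class, logical(1)))) {
        return(TRUE)
      }
    }
  }
  # left flank: trinucleotide at [start - 3, start), nonamer further left
  if (rh$start - 3 >= 0) {
    tri <- substr(seq, rh$start - 2L, rh$start)
    if (tri %in% c("GTG", "CAC")) {
      spacers <- (rh$start - 3L) - nh$end
      if (any(vapply(spacers, in_class, logical(1)))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' @rdname spatial_classify
#' @param records Spatial record tibble from [spatial_classify()].
#' @export
spatial_medians <- function(records) {
  records %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median_distance_bp = stats::median(.data$distance_bp),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$category)
}

#' ChIP-Seq peak RSS/RUNX1 enrichment
#'
#' Counts peaks containing at least one RSS module hit and, of those, peaks
#' in which a module heptamer overlaps a RUNX1 hit by at least the configured
#' overlap; enrichment is computed against the background RUNX1-overlap rate
#' among RSS-module windows of a background genome.
#'
#' @param peaks Peak regions (tibble with `sequence`).
#' @param background Counts from [scan_background_genome()].
#' @param models,runx1_pwm,config As elsewhere.
#' @param variance Variance model for [motif_enrichment()].
#' @return List with `n_peaks_with_rss`, `n_with_runx1_overlap` and
#'   `enrichment` (`vdj_enrichment`, or NULL when degenerate).
#' @export
chip_peak_rss_enrichment <- function(peaks, background,
                                     models = rss_models(),
                                     runx1_pwm = default_runx1_pwm(),
                                     config = vdj_config(),
                                     variance = "binomial") {
  if (nrow(peaks) == 0) {
    return(list(
      n_peaks_with_rss = 0L, n_with_runx1_overlap = 0L, enrichment = NULL
    ))
  }
  modules <- scan_rss_modules_regions(
    peaks, models,
    threshold_heptamer = config$similarity_threshold_heptamer,
    threshold_nonamer = config$similarity_threshold_nonamer
  )
  runx1 <- scan_regions(
    peaks, runx1_pwm,
    threshold = config$similarity_threshold_runx1
  )
  with_rss <- sort(unique(modules$region_id))
  positive <- vapply(with_rss, function(rid) {
    mh <- modules[modules$region_id == rid, ]
    rh <- runx1[runx1$region_id == rid, ]
    if (nrow(rh) == 0) {
      return(FALSE)
    }
    any(vapply(seq_len(nrow(mh)), function(k) {
      any(interval_overlap(
        rh$start, rh$end, mh$hept_start[k], mh$hept_end[k]
      ) >= config$min_runx1_heptamer_overlap)
    }, logical(1)))
  }, logical(1))
  n_rss <- length(with_rss)
  n_pos <- sum(positive)
  enr <- if (n_rss > 0 && background$n_rss_windows > 0) {
    motif_enrichment(
      n_pos, n_rss,
      background$n_rss_windows_runx1, background$n_rss_windows,
      variance = variance
    )
  } else {
    NULL
  }
  list(
    n_peaks_with_rss = n_rss, n_with_runx1_overlap = n_pos,
    enrichment = enr, modules = modules, runx1_hits = runx1
  )
}
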