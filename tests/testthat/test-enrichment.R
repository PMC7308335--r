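test_that("deletion-end region construction follows the 60 + 7 bp geometry", {
  genome <- c(chr1 = random_dna(4000, seed = 71))
  dels <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L)
  regions <- build_deletion_end_regions(dels, genome)
  expect_equal(nrow(regions), 2)
  five <- regions[regions$role == "deletion_5prime_end", ]
  three <- regions[regions$role == "deletion_3prime_end", ]
  expect_equal(c(five$start, five$end), c(993, 1060))
  expect_equal(c(three$start, three$end), c(1940, 2007))
  expect_equal(five$border_position, 1000)
  expect_equal(three$border_position, 2000)
  expect_true(all(regions$end - regions$start == 67))
  expect_true(all(nchar(regions$sequence) == 67))

  # 56 deletions give 112 regions
  dels56 <- tibble::tibble(
    chrom = "chr1", start = seq(100, by = 65, length.out = 56)
  )
  genome_big <- c(chr1 = random_dna(10000))
  dels56$end <- dels56$start + 60L
  # overlapping deletions are fine for the construction; count the output
  expect_equal(nrow(build_deletion_end_regions(dels56, genome_big)), 112)

  # deletion shorter than the inner span errors, clipping is flagged
  expect_error(
    build_deletion_end_regions(
      tibble::tibble(chrom = "chr1", start = 10L, end = 50L), genome
    ),
    "deletion 1"
  )
  expect_warning(
    clipped <- build_deletion_end_regions(
      tibble::tibble(chrom = "chr1", start = 5L, end = 100L), genome
    ),
    "clipped"
  )
  expect_true(any(clipped$clipped))
  expect_equal(clipped$start[clipped$role == "deletion_5prime_end"], 0)
})

test_that("heptamer windows expand by 7 nt, clip, merge, and merging is idempotent", {
  regions <- tibble::tibble(
    chrom = "r", start = 0L, end = 67L,
    sequence = random_dna(67, seed = 73),
    role = "deletion_5prime_end", border_position = 0L
  )
  hit <- function(s, rid = 1L) {
    tibble::tibble(
      region_id = rid, start = s, end = s + 7L, strand = "+",
      score = 1, matrix_name = "hept_d3"
    )
  }
  w1 <- extract_heptamer_windows(regions, hit(20L))
  expect_equal(c(w1$start, w1$end), c(13, 34))

  w2 <- extract_heptamer_windows(regions, dplyr::bind_rows(hit(20L), hit(25L)))
  expect_equal(nrow(w2), 1)
  expect_equal(c(w2$start, w2$end), c(13, 39))
  expect_equal(w2$n_hits, 2)

  w3 <- extract_heptamer_windows(regions, hit(2L))
  expect_equal(c(w3$start, w3$end), c(0, 16))

  # idempotence: merging the merged window set changes nothing
  merged_again <- vdjrss:::merge_intervals(w2$start, w2$end)
  expect_equal(merged_again$start, w2$start)
  expect_equal(merged_again$end, w2$end)

  # windows fully inside an RSS module are flagged through the heptamer hit
  mods <- tibble::tibble(
    region_id = 1L, model = "m", strand = "+",
    hept_start = 20L, hept_end = 27L, hept_score = 1,
    non_start = 39L, non_end = 48L, non_score = 1, spacer_len = 12L
  )
  w4 <- extract_heptamer_windows(regions, hit(20L), mods)
  expect_true(w4$in_rss_module)
})

test_that("RUNX1 window counting demands a 4-nt overlap with the heptamer hit itself", {
  regions <- tibble::tibble(
    chrom = "r", start = 0L, end = 67L,
    sequence = random_dna(67, seed = 79),
    role = "deletion_5prime_end", border_position = 0L
  )
  hept <- tibble::tibble(
    region_id = 1L, start = 17L, end = 24L, strand = "+",
    score = 1, matrix_name = "hept_d3"
  )
  windows <- extract_heptamer_windows(regions, hept)
  runx1_at <- function(s, e) {
    tibble::tibble(
      region_id = 1L, start = s, end = e, strand = "+",
      score = 0.9, matrix_name = "RUNX1"
    )
  }
  # [10, 21) vs heptamer [17, 24): overlap 4 -> positive
  expect_equal(
    count_runx1_overlaps(windows, runx1_at(10L, 21L))$n_windows_with_runx1, 1
  )
  # [10, 20): overlap 3 -> negative
  expect_equal(
    count_runx1_overlaps(windows, runx1_at(10L, 20L))$n_windows_with_runx1, 0
  )
  # a RUNX1 hit inside the window but missing the heptamer does not count
  expect_equal(
    count_runx1_overlaps(windows, runx1_at(25L, 36L))$n_windows_with_runx1, 0
  )
  empty <- runx1_at(10L, 21L)[0, ]
  expect_equal(count_runx1_overlaps(windows, empty)$n_windows_with_runx1, 0)
})

test_that("analytic enrichment reproduces its contract and the degenerate cases", {
  # observed equal to expected: fold 1, z 0
  e0 <- motif_enrichment(10, 50, 20, 100)
  expect_equal(e0$fold, 1)
  expect_equal(e0$z, 0)

  # binomial-variance z follows the continuity-corrected formula
  e1 <- motif_enrichment(15, 30, 76, 300)
  p <- 76 / 300
  expect_equal(e1$expected, 30 * p)
  expect_equal(e1$z, (15 - 7.6 - 0.5) / sqrt(30 * p * (1 - p)))
  expect_equal(e1$p_binomial, binomial_upper_tail(15, 30, p))

  # Poisson variance option reproduces sd = sqrt(expected)
  e2 <- motif_enrichment(15, 30, 76, 300, variance = "poisson")
  expect_equal(round(e2$z, 2), 2.5)
  expect_equal(round(e2$fold, 1), 2)

  # zero-rate background flags the fold undefined
  e3 <- motif_enrichment(3, 30, 0, 1000)
  expect_true(is.na(e3$fold))
  expect_equal(e3$z, Inf)

  # lower tail when observed is below expected
  e4 <- motif_enrichment(2, 50, 20, 100)
  expect_equal(e4$p_binomial, binomial_lower_tail(2, 50, 0.2))
})

test_that("analytic and resampling enrichment agree for expected >= 5", {
  set.seed(83)
  for (i in 1:12) {
    n_fg <- sample(30:120, 1)
    p <- stats::runif(1, 0.08, 0.4)
    if (n_fg * p < 5) next
    obs <- stats::rbinom(1, n_fg, min(1, p * 2))
    a <- motif_enrichment(obs, n_fg, round(p * 1000), 1000)
    r <- motif_enrichment(obs, n_fg, round(p * 1000), 1000,
      method = "resampling", n_resamples = 20000, seed = i
    )
    expect_lt(abs(a$z - r$z), 0.3)
    if (a$p_binomial > 1e-3) { # resampling resolution floor
      expect_lt(
        abs(log(a$p_binomial) - log(r$p_binomial)), log(2)
      )
    }
  }
})

test_that("spatial classification ranks categories and measures border distances", {
  tpl <- rss_site_templates()
  pad <- function(n, seed) random_dna(n, seed)
  # region of 67 nt, border at genomic coordinate 100 (5' end region)
  mkregion <- function(seq67) {
    tibble::tibble(
      chrom = "chr1", start = 93L, end = 160L, sequence = seq67,
      role = "deletion_5prime_end", border_position = 100L
    )
  }
  cfg <- vdj_config()
  scan_all <- function(regions) {
    models <- rss_models()
    list(
      hept = dplyr::bind_rows(
        scan_regions(regions, default_heptamer_pwms()$hept_d3),
        scan_regions(regions, default_heptamer_pwms()$hept_j5)
      ),
      mods = scan_rss_modules_regions(regions, models),
      runx1 = scan_regions(regions, default_runx1_pwm()),
      non = dplyr::bind_rows(
        scan_regions(regions, default_nonamer_pwms()$non_d3),
        scan_regions(regions, default_nonamer_pwms()$non_j5)
      )
    )
  }

  # planted RUNX1-in-RSS with RUNX1 start 6 bp beyond the border
  seq_rss <- paste0(
    substr(pad(67, 89), 1, 13), revcomp(tpl[["runx1_rss"]]),
    substr(pad(67, 90), 49, 67)
  )
  # revcomp(runx1_rss) has its RUNX1 site at template offset 0; region offset
  # 13 puts the RUNX1 start at genomic 93 + 13 = 106, i.e. distance 6
  reg <- mkregion(seq_rss)
  s <- scan_all(reg)
  rec <- spatial_classify(reg, s$runx1, s$hept, s$mods, s$non, cfg)
  hit6 <- rec[rec$distance_bp == 6, ]
  expect_gte(nrow(hit6), 1)
  expect_equal(unique(hit6$category), "RUNX1_RSS")

  # lone planted RUNX1 with neutral flanks: category RUNX1_only
  seq_only <- paste0(
    substr(pad(67, 91), 1, 10), tpl[["runx1_only"]],
    substr(pad(67, 92), 28, 67)
  )
  reg2 <- mkregion(seq_only)
  s2 <- scan_all(reg2)
  rec2 <- spatial_classify(reg2, s2$runx1, s2$hept, s2$mods, s2$non, cfg)
  planted2 <- rec2[rec2$start == 13, ] # runx1_offset 3 within the template
  expect_equal(unique(planted2$category), "RUNX1_only")

  # GTG flank + nonamer at spacer 12: partial category
  seq_partial <- paste0(
    substr(pad(67, 93), 1, 5), tpl[["runx1_partial"]],
    substr(pad(67, 94), 41, 67)
  )
  reg3 <- mkregion(seq_partial)
  s3 <- scan_all(reg3)
  rec3 <- spatial_classify(reg3, s3$runx1, s3$hept, s3$mods, s3$non, cfg)
  planted3 <- rec3[rec3$start == 5, ]
  expect_equal(
    unique(planted3$category), "RUNX1_partial_heptamer_nonamer"
  )

  # same arrangement at spacer 15 (outside {12} and 19-25): RUNX1_only
  seq_partial15 <- paste0(
    strrep("T", 5),
    "TGTGGTTTGTC", "GTG", "TCTAGATCGATAGCA", "ACAAAAACC",
    strrep("T", 24)
  )
  reg4 <- mkregion(seq_partial15)
  s4 <- scan_all(reg4)
  rec4 <- spatial_classify(reg4, s4$runx1, s4$hept, s4$mods, s4$non, cfg)
  planted4 <- rec4[rec4$start == 5, ]
  expect_equal(unique(planted4$category), "RUNX1_only")
})

test_that("planted cohort distances are recovered as per-category medians", {
  g <- simulate_genome(genome_sim_params(length = 60000, gc = 0.41, seed = 101))
  plan <- tibble::tibble(
    class = c("runx1_rss", "runx1_only"),
    fraction = c(0.5, 0.3),
    distance = c(6, 21)
  )
  coh <- simulate_deletion_cohort(g$genome, 40, plan = plan, seed = 7)
  regions <- build_deletion_end_regions(coh$deletions, coh$genome)
  models <- rss_models()
  hept <- dplyr::bind_rows(
    scan_regions(regions, default_heptamer_pwms()$hept_d3),
    scan_regions(regions, default_heptamer_pwms()$hept_j5)
  )
  hept <- hept[!duplicated(paste(hept$region_id, hept$start, hept$strand)), ]
  mods <- scan_rss_modules_regions(regions, models)
  runx1 <- scan_regions(regions, default_runx1_pwm())
  non <- dplyr::bind_rows(
    scan_regions(regions, default_nonamer_pwms()$non_d3),
    scan_regions(regions, default_nonamer_pwms()$non_j5)
  )
  rec <- spatial_classify(regions, runx1, hept, mods, non)
  med <- spatial_medians(rec)
  expect_equal(
    med$median_distance_bp[med$category == "RUNX1_RSS"], 6
  )
  only <- rec[rec$category == "RUNX1_only", ]
  # planted RUNX1-only sites dominate the category; background hits may add
  expect_equal(stats::median(only$distance_bp[only$score == 1]), 21)
})

test_that("ChIP-peak RSS enrichment counts peaks and reduces to a fold/Z result", {
  empty <- chip_peak_rss_enrichment(
    tibble::tibble(sequence = character()),
    background = list(n_rss_windows = 10, n_rss_windows_runx1 = 2)
  )
  expect_equal(empty$n_peaks_with_rss, 0)
  expect_null(empty$enrichment)

  # 30 synthetic peaks: 15 planted with RUNX1-overlapping modules, 15 with
  # plain RSS modules; background rate tuned so expected ~ 7.6
  tpl <- rss_site_templates()
  set.seed(103)
  mkpeak <- function(core) {
    paste0(random_dna(40), core, random_dna(40))
  }
  peaks <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 0L,
    sequence = c(
      vapply(1:15, function(i) mkpeak(tpl[["runx1_rss"]]), character(1)),
      vapply(1:15, function(i) mkpeak(tpl[["rss"]]), character(1))
    ),
    role = "peak", border_position = NA_integer_
  )
  bg <- list(n_rss_windows = 1000, n_rss_windows_runx1 = 253)
  res <- chip_peak_rss_enrichment(peaks, bg, variance = "poisson")
  expect_gte(res$n_peaks_with_rss, 28)
  expect_gte(res$n_with_runx1_overlap, 14)
  expect_equal(round(res$enrichment$fold), 2)
  expect_gt(res$enrichment$z, 2)
})

test_that("null calibration: foreground drawn from background rarely exceeds Z 2", {
  set.seed(107)
  n_fg <- 65
  p <- 0.2
  z <- replicate(400, {
    motif_enrichment(stats::rbinom(1, n_fg, p), n_fg, 200, 1000)$z
  })
  expect_lte(mean(z > 2), 0.05)
  expect_gte(mean(z > 2), 0) # one-sided tail, bounded below trivially
})
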