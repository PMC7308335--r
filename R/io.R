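#' Read paired-end FASTQ files
#'
#' Reads matched R1/R2 FASTQ files (4-line records, Phred+33 qualities) into a
#' tibble of read pairs. Records are paired by file order; a truncated record
#' or a sequence/quality length mismatch raises a parse error naming the
#' offending record.
#'
#' @param path_r1,path_r2 Paths to the R1 and R2 FASTQ files.
#' @return A tibble with columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`;
#'   qualities are integer vectors in list-columns.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf(
      "R1/R2 record count mismatch at record %d (%s has %d records, %s has %d)",
      min(nrow(r1), nrow(r2)) + 1L, path_r1, nrow(r1), path_r2, nrow(r2)
    ))
  }
  tibble(
    read_id = sub("^@", "", r1$id),
    seq1 = r1$seq, qual1 = r1$qual,
    seq2 = r2$seq, qual2 = r2$qual
  )
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(id = character(), seq = character(), qual = list()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf(
      "truncated FASTQ record %d in %s", length(lines) %/% 4 + 1L, path
    ))
  }
  idx <- seq(1, length(lines), by = 4)
  ids <- lines[idx]
  seqs <- toupper(lines[idx + 1])
  quals <- lines[idx + 3]
  bad_hdr <- which(!startsWith(ids, "@"))
  if (length(bad_hdr) > 0) {
    abort(sprintf("malformed FASTQ header at record %d in %s", bad_hdr[1], path))
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len) > 0) {
    abort(sprintf(
      "sequence/quality length mismatch at record %d in %s", bad_len[1], path
    ))
  }
  tibble(
    id = ids, seq = seqs,
    qual = lapply(quals, function(q) utf8ToInt(q) - 33L)
  )
}

#' Write paired-end FASTQ files
#'
#' Inverse of [read_fastq_pairs()]; Phred+33 encoding.
#'
#' @param pairs A tibble as returned by [read_fastq_pairs()].
#' @param path_r1,path_r2 Output paths.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  write_fastq_one(pairs$read_id, pairs$seq1, pairs$qual1, path_r1)
  write_fastq_one(pairs$read_id, pairs$seq2, pairs$qual2, path_r2)
  invisible(c(path_r1, path_r2))
}

write_fastq_one <- function(ids, seqs, quals, path) {
  qstr <- vapply(quals, function(q) intToUtf8(q + 33L), character(1))
  if (length(ids) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rec <- as.vector(rbind(paste0("@", ids), seqs, "+", qstr))
  writeLines(rec, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector, one uppercase sequence per chromosome.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read BED-like regions and attach genome sequence
#'
#' Coordinates are 0-based half-open (BED convention), the package-wide
#' interval convention. Each region is populated with its uppercase genomic
#' sequence.
#'
#' @param path Whitespace- or tab-separated file with columns chrom, start,
#'   end (further columns ignored).
#' @param genome Named character vector (see [read_genome_fasta()]).
#' @param role Region role label recorded on every row.
#' @return A tibble with columns `chrom`, `start`, `end`, `sequence`, `role`,
#'   `border_position` (NA).
#' @export
read_regions <- function(path, genome, role = "other") {
  if (!file.exists(path)) abort(sprintf("regions file not found: %s", path))
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      sequence = character(), role = character(), border_position = integer()
    ))
  }
  if (ncol(raw) < 3) abort("regions file needs at least 3 columns (chrom, start, end)")
  regions <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  bad <- which(regions$start >= regions$end)
  if (length(bad) > 0) {
    abort(sprintf("start >= end at line %d of %s", bad[1], path))
  }
  regions_with_sequence(regions, genome, role = role)
}

# Attach sequence (and role / border bookkeeping) to a chrom/start/end tibble.
regions_with_sequence <- function(regions, genome, role = "other") {
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss) > 0) {
    abort(sprintf("chrom absent from genome: %s", miss[1]))
  }
  too_long <- regions$end > nchar(genome[regions$chrom])
  if (any(too_long)) {
    abort(sprintf(
      "region beyond chromosome end: %s:%d-%d",
      regions$chrom[which(too_long)[1]], regions$start[which(too_long)[1]],
      regions$end[which(too_long)[1]]
    ))
  }
  regions$sequence <- unname(substr(
    genome[regions$chrom], regions$start + 1L, regions$end
  ))
  if (!"role" %in% names(regions)) regions$role <- role
  if (!"border_position" %in% names(regions)) regions$border_position <- NA_integer_
  regions
}

#' Write regions as BED
#'
#' @param regions Tibble with `chrom`, `start`, `end` (plus optional columns,
#'   ignored).
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")],
    file = path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
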