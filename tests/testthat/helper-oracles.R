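# Independent oracles used across the suite. These deliberately re-derive
# results by enumeration / direct formula application, sharing no code with
# the scanning, testing or decomposition paths they check.

BASES <- c("A", "C", "G", "T")

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

# direct-formula similarity of a single window against a pwm object
oracle_similarity <- function(pwm, window) {
  ch <- strsplit(window, "")[[1]]
  num <- 0
  den <- 0
  for (i in seq_len(pwm$width)) {
    b <- match(ch[i], BASES)
    if (is.na(b)) {
      return(0)
    }
    num <- num + pwm$weights[i] * pwm$freqs[b, i]
    den <- den + pwm$weights[i] * max(pwm$freqs[, i])
  }
  if (den <= 0) 0 else unname(num / den)
}

# score every window at every offset and strand by brute force
oracle_scan <- function(sequence, pwm, threshold) {
  L <- nchar(sequence)
  w <- pwm$width
  rows <- list()
  for (start0 in 0:(L - w)) {
    win <- substr(sequence, start0 + 1, start0 + w)
    s_plus <- oracle_similarity(pwm, win)
    if (s_plus >= threshold) {
      rows[[length(rows) + 1]] <- data.frame(
        start = start0, end = start0 + w, strand = "+", score = s_plus
      )
    }
    s_minus <- oracle_similarity(pwm, oracle_revcomp(win))
    if (s_minus >= threshold) {
      rows[[length(rows) + 1]] <- data.frame(
        start = start0, end = start0 + w, strand = "-", score = s_minus
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(
      start = integer(), end = integer(),
      strand = character(), score = numeric()
    ))
  }
  out[order(out$start, out$strand), ]
}

# full-enumeration two-tailed Fisher p (point-probability rule)
oracle_fisher <- function(a, b, c, d) {
  k <- a + c # column-1 margin
  xs <- max(0, k - (c + d)):min(a + b, k)
  probs <- stats::dhyper(xs, a + b, c + d, k)
  p_obs <- stats::dhyper(a, a + b, c + d, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# full-enumeration exact two-tailed Mann-Whitney p for tie-free samples
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  u_obs <- sum(outer(x, y, ">"))
  splits <- utils::combn(n, m)
  us <- apply(splits, 2, function(idx) {
    xa <- pooled[idx]
    yb <- pooled[-idx]
    sum(outer(xa, yb, ">"))
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force D assignment: enumerate all (D, junction placement, length)
# exact matches and apply the tie rules directly
oracle_d_assignment <- function(junction, d_seqs, min_d = 5) {
  best <- NULL
  jl <- nchar(junction)
  for (dn in sort(names(d_seqs))) {
    dseq <- d_seqs[[dn]]
    for (start in seq_len(max(jl - min_d + 1, 0))) {
      max_len <- min(jl - start + 1, nchar(dseq))
      if (max_len < min_d) next
      for (len in seq(max_len, min_d)) {
        sub <- substr(junction, start, start + len - 1)
        hit <- regexpr(sub, dseq, fixed = TRUE)
        if (hit > 0) {
          cand <- list(
            d_name = dn, start = start, len = len, pos_in_d = as.integer(hit)
          )
          if (is.null(best) || cand$len > best$len) best <- cand
          break
        }
      }
    }
  }
  best
}

# reconstruct a CDR3 from its reported architecture and the germline registry
reconstruct_cdr3 <- function(row, registry) {
  v <- registry[registry$name == row$v_name, ]
  j <- registry[registry$name == row$j_name, ]
  vg <- substr(v$sequence, v$anchor_offset + 1, nchar(v$sequence))
  jg <- substr(j$sequence, 1, j$anchor_offset + 3)
  kept_v <- substr(vg, 1, nchar(vg) - row$v_trunc)
  kept_j <- substr(jg, row$j_trunc + 1, nchar(jg))
  if (is.na(row$d_name)) {
    paste0(kept_v, row$n1_seq, kept_j)
  } else {
    d <- registry[registry$name == row$d_name, ]
    kept_d <- substr(
      d$sequence, row$d5_trunc + 1, nchar(d$sequence) - row$d3_trunc
    )
    paste0(kept_v, row$n1_seq, kept_d, row$n2_seq, kept_j)
  }
}

clonotype_key <- function(tbl) paste(tbl$v_name, tbl$j_name, tbl$cdr3_nt)

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}
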