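# Independent brute-force oracles, deliberately naive: a double loop over
# every offset and strand for motif matching, and quadratic all-pairs
# interval scans. They share no code with the package internals.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  N = c("A", "C", "G", "T", "N")  # sequence N matches only pattern N
)

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_matches <- function(substring, symbols) {
  chars <- strsplit(substring, "", fixed = TRUE)[[1]]
  all(mapply(function(ch, sy) ch %in% ORACLE_SETS[[sy]], chars, symbols))
}

# All occurrences of the degenerate consensus, every offset, both strands.
oracle_scan <- function(seq, consensus = "GGGRNNYYCC") {
  symbols <- strsplit(consensus, "", fixed = TRUE)[[1]]
  L <- length(symbols)
  n <- nchar(seq)
  rows <- list()
  if (n >= L) {
    for (s in 0:(n - L)) {
      sub <- substr(seq, s + 1, s + L)
      if (oracle_matches(sub, symbols)) {
        rows[[length(rows) + 1]] <- data.frame(
          start = s, end = s + L, strand = "+", matched_seq = sub,
          stringsAsFactors = FALSE)
      }
      if (oracle_matches(oracle_revcomp(sub), symbols)) {
        rows[[length(rows) + 1]] <- data.frame(
          start = s, end = s + L, strand = "-", matched_seq = sub,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), matched_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Quadratic nearest-distance scan (0 inside the interval, gap+1 semantics
# matching "k bases away" counting).
oracle_nearest_distance <- function(pos, contig, occurrences) {
  occ <- occurrences[occurrences$contig == contig, , drop = FALSE]
  if (nrow(occ) == 0) return(Inf)
  min(vapply(seq_len(nrow(occ)), function(i) {
    max(0, occ$start[i] - pos, pos - occ$end[i] + 1)
  }, numeric(1)))
}

# Quadratic all-pairs interval overlap (half-open intervals).
oracle_overlaps_any <- function(qs, qe, starts, ends) {
  any(qs < ends & starts < qe)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Expand a genotype_counts object into subject rows (no covariates).
subjects_from_counts <- function(gc) {
  m <- gc$counts
  rows <- list()
  for (grp in rownames(m)) {
    for (g in colnames(m)) {
      k <- m[grp, g]
      if (k > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          group = grp, genotype = g, stringsAsFactors = FALSE)[rep(1, k), ]
      }
    }
  }
  out <- do.call(rbind, rows)
  out$id <- sprintf("S%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
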