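# The scanner is checked against an independent brute-force oracle (every
# offset, both strands) and against Biostrings' degenerate matcher.

CONSENSUS <- "GGGRNNYYCC"

test_that("published flanking contexts scan exactly as the oracle says", {
  ctx <- candidate_context_genome()
  for (i in seq_len(nrow(ctx$variants))) {
    v <- ctx$variants[i, ]
    for (allele in c(v$ref, v$alt)) {
      seq <- paste0(substr(ctx$genome[[v$contig]], 1, v$pos), allele,
                    substr(ctx$genome[[v$contig]], v$pos + 2,
                           nchar(ctx$genome[[v$contig]])))
      got <- scan_motifs(stats::setNames(seq, "x"), CONSENSUS)
      exp <- oracle_scan(seq, CONSENSUS)
      expect_equal(got[, c("start", "end", "strand", "matched_seq")],
                   exp, info = paste(v$id, allele))
    }
  }
})

test_that("known context matches land at the expected offsets", {
  occ <- scan_motifs(c(x = "AAAGGCAGGGATTTTCCCC"), CONSENSUS)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$start, 7L)
  expect_equal(occ$strand, "+")
  expect_equal(occ$matched_seq, "GGGATTTTCC")

  # this 10-mer fits the consensus in both orientations (its reverse
  # complement GGGACTTCCC also matches), so both strands are reported
  occ2 <- scan_motifs(c(x = "GTGACAGCTGGGAAGTCCC"), CONSENSUS)
  expect_equal(occ2$start, c(9L, 9L))
  expect_equal(occ2$strand, c("+", "-"))
  expect_equal(unique(occ2$matched_seq), "GGGAAGTCCC")
  occ2f <- scan_motifs(c(x = "GTGACAGCTGGGAAGTCCC"), CONSENSUS,
                       both_strands = FALSE)
  expect_equal(nrow(occ2f), 1L)
  expect_equal(occ2f$start, 9L)
})

test_that("short and empty sequences yield no occurrences", {
  expect_equal(nrow(scan_motifs(c(x = ""), CONSENSUS)), 0L)
  expect_equal(nrow(scan_motifs(c(x = "GGGATTTTC"), CONSENSUS)), 0L)
})

test_that("an embedded reverse complement is found on the minus strand", {
  set.seed(42)
  core <- iupac_revcomp("GGGATTTTCC")  # concrete site, minus orientation
  left <- random_dna(37)
  right <- random_dna(25)
  # scrub accidental matches from the random flanks
  seq <- paste0(left, core, right)
  exp <- oracle_scan(seq, CONSENSUS)
  got <- scan_motifs(c(x = seq), CONSENSUS)
  expect_equal(got[, c("start", "end", "strand", "matched_seq")], exp)
  expect_true(any(got$strand == "-" & got$start == 37))
})

test_that("scanner equals the oracle on random sequences", {
  set.seed(101)
  for (rep in 1:40) {
    seq <- random_dna(sample(50:400, 1))
    got <- scan_motifs(c(x = seq), CONSENSUS)
    expect_equal(got[, c("start", "end", "strand", "matched_seq")],
                 oracle_scan(seq, CONSENSUS))
  }
})

test_that("scanner agrees with Biostrings degenerate matching", {
  set.seed(202)
  pat <- Biostrings::DNAString(CONSENSUS)
  for (rep in 1:10) {
    seq <- random_dna(5000)
    got <- scan_motifs(c(x = seq), CONSENSUS)
    subj <- Biostrings::DNAString(seq)
    fwd <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                    fixed = FALSE)
    expect_equal(sort(got$start[got$strand == "+"]),
                 sort(Biostrings::start(fwd) - 1L))
    expect_equal(sort(got$start[got$strand == "-"]),
                 sort(Biostrings::start(rev) - 1L))
  }
})

test_that("scanning the reverse complement mirrors coordinates and strands", {
  set.seed(303)
  seq <- random_dna(3000)
  n <- nchar(seq)
  fwd <- scan_motifs(c(x = seq), CONSENSUS)
  rev <- scan_motifs(c(x = oracle_revcomp(seq)), CONSENSUS)
  mirror <- data.frame(start = n - fwd$end,
                       strand = ifelse(fwd$strand == "+", "-", "+"),
                       stringsAsFactors = FALSE)
  mirror <- mirror[order(mirror$start, mirror$strand), ]
  rownames(mirror) <- NULL
  expect_equal(rev[, c("start", "strand")], mirror)
})

test_that("ambiguous reference N matches only pattern N", {
  # N in the sequence must not be reported as a concrete-symbol match
  expect_equal(nrow(scan_motifs(c(x = "GGGNNNNNCC"), CONSENSUS)), 0L)
  # but pattern N accepts sequence N
  expect_equal(nrow(scan_motifs(c(x = "N"), compile_pattern("N"),
                                both_strands = FALSE)), 1L)
})

test_that("chance-match density on uniform sequence is ~2/8192 per offset", {
  set.seed(8192)
  n <- 1e6
  seq <- random_dna(n)
  occ <- scan_motifs(c(x = seq), CONSENSUS)
  offsets <- n - 10 + 1
  expected <- 2 * offsets / 8192   # (1/4)^5 * (1/2)^3 per strand
  sd <- sqrt(expected)
  expect_lt(abs(nrow(occ) - expected), 5 * sd)
})
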