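## Degenerate motif scanning and allele-effect classification.
##
## Coordinates are 0-based half-open throughout ([start, end), BED-style);
## VCF positions are converted once, at parse time (see read_variants_vcf).

## Coerce a genome argument (named character vector or Biostrings
## DNAStringSet) to a named character vector of contig sequences.
.as_contig_vector <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome) || is.null(names(genome)) || anyNA(names(genome))) {
    stop("'genome' must be a named character vector or DNAStringSet of contigs")
  }
  genome
}

## All 0-based offsets in an encoded sequence where the pattern matches.
.scan_encoded <- function(code, pattern) {
  n <- length(code)
  L <- pattern$length
  if (n < L) return(integer(0))
  ok <- pattern$allow[[1L]][code[seq_len(n - L + 1L)]]
  if (L > 1L) {
    for (j in 2L:L) {
      ok <- ok & pattern$allow[[j]][code[j:(n - L + j)]]
    }
  }
  which(ok) - 1L
}

.empty_occurrences <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), matched_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Scan sequences for occurrences of a degenerate motif
#'
#' Finds every offset, on one or both strands, where a degenerate IUPAC
#' consensus matches. A minus-strand occurrence is a forward-strand interval
#' whose reverse complement matches the pattern; `matched_seq` is always the
#' sequence as read on the forward strand. Overlapping matches are all
#' reported, and an interval matching on both strands yields two records.
#'
#' @param genome Named character vector of contig sequences (A/C/G/T/N), or a
#'   `Biostrings::DNAStringSet`.
#' @param pattern An [`iupac_pattern`][compile_pattern], or a consensus string
#'   which is compiled on the fly.
#' @param both_strands Scan the minus strand as well (default `TRUE`). The
#'   NF-kB consensus is not its own reverse complement, so the two strands
#'   are genuinely distinct searches.
#' @return A data frame with columns `contig`, `start` (0-based inclusive),
#'   `end` (exclusive, `start + pattern length`), `strand` (`"+"`/`"-"`) and
#'   `matched_seq`, sorted by (contig, start, strand).
#' @examples
#' scan_motifs(c(chr1 = "AAAGGCAGGGATTTTCCCC"), "GGGRNNYYCC")
#' @export
scan_motifs <- function(genome, pattern, both_strands = TRUE) {
  genome <- .as_contig_vector(genome)
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  stopifnot(inherits(pattern, "iupac_pattern"))
  rc_pattern <- if (both_strands) compile_pattern(iupac_revcomp(pattern$consensus)) else NULL

  per_contig <- lapply(names(genome), function(ctg) {
    seq <- genome[[ctg]]
    if (nchar(seq) < pattern$length) return(.empty_occurrences())
    code <- .encode_seq(seq)
    starts <- .scan_encoded(code, pattern)
    strands <- rep("+", length(starts))
    if (both_strands) {
      mstarts <- .scan_encoded(code, rc_pattern)
      starts <- c(starts, mstarts)
      strands <- c(strands, rep("-", length(mstarts)))
    }
    if (length(starts) == 0L) return(.empty_occurrences())
    ord <- order(starts, strands)
    starts <- starts[ord]; strands <- strands[ord]
    data.frame(contig = ctg,
               start = as.integer(starts),
               end = as.integer(starts + pattern$length),
               strand = strands,
               matched_seq = substring(seq, starts + 1L, starts + pattern$length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_contig)
  rownames(out) <- NULL
  out
}

## Substitute a single base at 0-based position pos of a contig string.
.substitute_base <- function(seq, pos, base) {
  paste0(substr(seq, 1L, pos), base, substr(seq, pos + 2L, nchar(seq)))
}

#' Classify the effect of a SNV allele on motif occurrences
#'
#' Evaluates the local window `[pos - (L - 1), pos + L)` (clipped to contig
#' bounds, `L` = pattern length) twice: once with the reference allele
#' substituted at the variant position and once with the alternate allele.
#' Only occurrences that *cover* the variant position are compared:
#' \describe{
#'   \item{`SITE_PRESERVED`}{both alleles leave at least one covering
#'     occurrence;}
#'   \item{`SITE_DESTROYED`}{the reference allele supports a covering
#'     occurrence that the alternate allele abolishes;}
#'   \item{`SITE_CREATED`}{the alternate allele creates a covering occurrence
#'     absent on the reference allele;}
#'   \item{`NO_SITE`}{neither allele yields a covering occurrence.}
#' }
#' Swapping `ref` and `alt` exchanges `SITE_DESTROYED` and `SITE_CREATED`
#' and fixes the other two labels.
#'
#' @param variant A list or one-row data frame with elements `contig`, `pos`
#'   (0-based), `ref`, `alt` (single bases: only SNVs are supported).
#' @param genome Named character vector of contigs or `DNAStringSet`.
#' @param pattern An [`iupac_pattern`][compile_pattern] or consensus string.
#' @param both_strands Passed to [scan_motifs()].
#' @return An object of class `"allele_effect"`: list with `effect` (one of
#'   the four labels), `ref_occurrences` and `alt_occurrences` (covering
#'   occurrences in genome coordinates), and `cov_start`/`cov_end`, the hull
#'   of all covering occurrences under either allele (`NA` for `NO_SITE`).
#' @export
classify_allele_effect <- function(variant, genome, pattern, both_strands = TRUE) {
  genome <- .as_contig_vector(genome)
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  v <- as.list(variant)
  if (nchar(v$ref) != 1L || nchar(v$alt) != 1L) {
    stop(sprintf("classify_allele_effect supports SNVs only (got ref '%s', alt '%s')",
                 v$ref, v$alt))
  }
  ctg <- as.character(v$contig)
  if (!ctg %in% names(genome)) stop("unknown contig: ", ctg)
  seq <- genome[[ctg]]
  pos <- as.integer(v$pos)
  if (pos < 0L || pos >= nchar(seq)) {
    stop(sprintf("position %d out of bounds for contig %s (length %d)",
                 pos, ctg, nchar(seq)))
  }
  L <- pattern$length
  ws <- max(0L, pos - (L - 1L))
  we <- min(nchar(seq), pos + L)
  window <- substr(seq, ws + 1L, we)
  rel <- pos - ws

  covering <- function(allele) {
    w <- .substitute_base(window, rel, toupper(allele))
    occ <- scan_motifs(stats::setNames(w, ctg), pattern, both_strands = both_strands)
    occ <- occ[occ$start <= rel & rel < occ$end, , drop = FALSE]
    occ$start <- occ$start + ws
    occ$end <- occ$end + ws
    rownames(occ) <- NULL
    occ
  }
  ref_occ <- covering(v$ref)
  alt_occ <- covering(v$alt)
  effect <-
    if (nrow(ref_occ) > 0L && nrow(alt_occ) > 0L) "SITE_PRESERVED"
    else if (nrow(ref_occ) > 0L) "SITE_DESTROYED"
    else if (nrow(alt_occ) > 0L) "SITE_CREATED"
    else "NO_SITE"
  all_occ <- rbind(ref_occ, alt_occ)
  structure(
    list(variant = v,
         effect = effect,
         ref_occurrences = ref_occ,
         alt_occurrences = alt_occ,
         cov_start = if (nrow(all_occ) > 0L) min(all_occ$start) else NA_integer_,
         cov_end = if (nrow(all_occ) > 0L) max(all_occ$end) else NA_integer_),
    class = "allele_effect"
  )
}

#' @export
print.allele_effect <- function(x, ...) {
  cat(sprintf("%s:%d %s>%s  %s  (ref: %d covering, alt: %d covering)\n",
              x$variant$contig, x$variant$pos, x$variant$ref, x$variant$alt,
              x$effect, nrow(x$ref_occurrences), nrow(x$alt_occurrences)))
  invisible(x)
}

#' Retain variants within a window of any motif occurrence
#'
#' Distance from a variant position to an occurrence interval `[s, e)` is 0
#' inside the interval, `s - pos` to the left and `pos - e + 1` to the right,
#' so a variant exactly `window` bases from the nearest interval edge is
#' retained. Mirrors a +/- 500 kb proximity screen around binding sites.
#'
#' @param variants Data frame with columns `contig`, `pos` (0-based).
#' @param occurrences Data frame as returned by [scan_motifs()].
#' @param window Maximum distance in bases (default 500000).
#' @return The retained subset of `variants` with an added
#'   `nearest_distance` column.
#' @export
snps_near_occurrences <- function(variants, occurrences, window = 500000L) {
  if (nrow(variants) == 0L) {
    variants$nearest_distance <- integer(0)
    return(variants)
  }
  d <- vapply(seq_len(nrow(variants)), function(i) {
    occ <- occurrences[occurrences$contig == variants$contig[i], , drop = FALSE]
    if (nrow(occ) == 0L) return(Inf)
    pos <- variants$pos[i]
    min(pmax(0, pmax(occ$start - pos, pos - occ$end + 1)))
  }, numeric(1))
  out <- variants[d <= window, , drop = FALSE]
  out$nearest_distance <- d[d <= window]
  rownames(out) <- NULL
  out
}

#' Retain variants positionally contained in a motif occurrence
#'
#' Half-open containment: a variant at the occurrence start is inside, one at
#' the exclusive end coordinate is not. Either strand counts.
#'
#' @inheritParams snps_near_occurrences
#' @return The retained subset of `variants`.
#' @export
snps_in_occurrences <- function(variants, occurrences) {
  if (nrow(variants) == 0L) return(variants)
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    occ <- occurrences[occurrences$contig == variants$contig[i], , drop = FALSE]
    if (nrow(occ) == 0L) return(FALSE)
    q <- IRanges::IRanges(start = variants$pos[i] + 1L, width = 1L)
    s <- IRanges::IRanges(start = occ$start + 1L, end = occ$end)
    length(IRanges::findOverlaps(q, s)) > 0L
  }, logical(1))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flanking-sequence context string for a SNV
#'
#' Builds the `LEFT[REF/ALT]RIGHT` display string with `flank` bases either
#' side of the variant, clipped at contig edges. Substituting REF back into
#' the brackets reproduces the reference window.
#'
#' @param variant List or one-row data frame with `contig`, `pos` (0-based),
#'   `ref`, `alt`.
#' @param genome Named character vector of contigs or `DNAStringSet`.
#' @param flank Bases of context either side (default 9).
#' @return An object of class `"snp_context"`: list with `context_string`,
#'   `left`, `right` and the variant fields.
#' @examples
#' g <- c(chr1 = "AAAGGCAGGGATTTTCCCC")
#' context_string(list(contig = "chr1", pos = 9, ref = "G", alt = "C"), g)
#' @export
context_string <- function(variant, genome, flank = 9L) {
  genome <- .as_contig_vector(genome)
  v <- as.list(variant)
  ctg <- as.character(v$contig)
  if (!ctg %in% names(genome)) stop("unknown contig: ", ctg)
  seq <- genome[[ctg]]
  pos <- as.integer(v$pos)
  if (pos < 0L || pos >= nchar(seq)) {
    stop(sprintf("position %d out of bounds for contig %s (length %d)",
                 pos, ctg, nchar(seq)))
  }
  left <- substr(seq, max(1L, pos - flank + 1L), pos)
  right <- substr(seq, pos + 2L, min(nchar(seq), pos + 1L + flank))
  structure(
    list(variant = v, flank = as.integer(flank), left = left, right = right,
         context_string = sprintf("%s[%s/%s]%s", left, toupper(v$ref),
                                  toupper(v$alt), right)),
    class = "snp_context"
  )
}

#' @export
print.snp_context <- function(x, ...) {
  cat(x$context_string, "\n")
  invisible(x)
}
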