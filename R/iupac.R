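## IUPAC degenerate nucleotide code: symbol -> set of concrete bases.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

## Sequence encoding used by the scanner: A,C,G,T,N -> 1..5.
.SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Compile a degenerate IUPAC consensus into a scannable pattern
#'
#' Resolves each symbol of a degenerate consensus (e.g. the NF-kB binding
#' consensus `"GGGRNNYYCC"`, where R = A/G, Y = C/T, N = any base) into its
#' set of allowed bases, precomputing the lookup tables used by
#' [scan_motifs()].
#'
#' An ambiguous reference base `N` in a scanned sequence matches only the
#' pattern symbol `N`, never a more specific symbol: a run of unknown
#' reference sequence is not reported as a binding site.
#'
#' @param consensus Single string over the IUPAC nucleotide alphabet
#'   (A, C, G, T plus the degenerate codes R, Y, S, W, K, M, B, D, H, V, N).
#' @return An object of class `"iupac_pattern"`: a list with elements
#'   `consensus` (the input string), `length`, `base_sets` (per-position
#'   character vectors of allowed bases), and internal match tables.
#' @examples
#' p <- compile_pattern("GGGRNNYYCC")
#' p$length
#' p$base_sets[[4]]  # R = A or G
#' @export
compile_pattern <- function(consensus) {
  if (!is.character(consensus) || length(consensus) != 1L || is.na(consensus) ||
      nchar(consensus) < 1L) {
    stop("'consensus' must be a single non-empty string")
  }
  symbols <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- which(!(symbols %in% names(.IUPAC_SETS)))
  if (length(bad) > 0L) {
    stop(sprintf("unsupported symbol '%s' at position %d of consensus '%s'",
                 symbols[bad[1L]], bad[1L], consensus))
  }
  base_sets <- .IUPAC_SETS[symbols]
  names(base_sets) <- NULL
  ## allow[[j]][code] : does sequence code (1..5 = A,C,G,T,N) satisfy
  ## pattern position j?  Sequence N matches only pattern N.
  allow <- lapply(seq_along(symbols), function(j) {
    v <- .SEQ_ALPHABET %in% base_sets[[j]]
    v[5L] <- identical(symbols[j], "N")
    v
  })
  structure(
    list(consensus = paste(symbols, collapse = ""),
         symbols = symbols,
         length = length(symbols),
         base_sets = base_sets,
         allow = allow),
    class = "iupac_pattern"
  )
}

#' @export
print.iupac_pattern <- function(x, ...) {
  cat(sprintf("IUPAC pattern %s (length %d)\n", x$consensus, x$length))
  invisible(x)
}

#' Reverse complement of an IUPAC string
#'
#' Complements degenerate symbols set-wise (R <-> Y, N -> N, ...) and
#' reverses. Works on concrete sequences as well.
#'
#' @param x Single string over the IUPAC alphabet.
#' @return The reverse-complement string.
#' @examples
#' iupac_revcomp("GGGRNNYYCC")  # "GGRRNNYCCC"
#' @export
iupac_revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  comp <- .IUPAC_COMPLEMENT[s]
  if (anyNA(comp)) {
    stop("cannot reverse-complement symbol(s): ",
         paste(unique(s[is.na(comp)]), collapse = ", "))
  }
  paste(rev(unname(comp)), collapse = "")
}

## Encode an A/C/G/T/N string as integer codes 1..5; errors on anything else.
.encode_seq <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(chars, .SEQ_ALPHABET)
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    stop("sequence contains non-ACGTN character(s): ",
         paste(bad, collapse = ", "))
  }
  code
}
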