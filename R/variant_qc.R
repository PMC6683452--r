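## Screening step 1: structural-variant removal and call-rate filter, then
## (after the motif stage) the minor-allele-frequency filter.
##
## Variant tables are plain data frames with columns:
##   contig, pos (0-based), id, ref, alt (comma-separated for multi-allelic),
##   variant_class ("SNV"/"INDEL"), call_rate, maf.

#' Classify a variant record as SNV or INDEL
#'
#' A record is an SNV iff the reference allele and every alternate allele
#' have length 1; anything else (insertions, deletions, MNVs) is INDEL and
#' is removed by the structural-variant filter, since such variants cannot
#' be carried through mass-array genotyping.
#'
#' @param ref Reference allele string.
#' @param alts Character vector of alternate alleles (a single
#'   comma-separated string is also accepted).
#' @return `"SNV"` or `"INDEL"`.
#' @examples
#' classify_variant("A", "G")        # SNV
#' classify_variant("AT", "A")       # INDEL
#' classify_variant("A", c("G","T")) # multi-allelic SNV
#' @export
classify_variant <- function(ref, alts) {
  if (length(alts) == 1L && grepl(",", alts, fixed = TRUE)) {
    alts <- strsplit(alts, ",", fixed = TRUE)[[1]]
  }
  if (length(ref) != 1L || is.na(ref) || !nzchar(ref) ||
      length(alts) < 1L || anyNA(alts) || any(!nzchar(alts))) {
    stop("malformed variant record: empty REF or ALT allele")
  }
  if (nchar(ref) == 1L && all(nchar(alts) == 1L)) "SNV" else "INDEL"
}

#' Structural-variant and call-rate quality control
#'
#' Retains SNVs whose per-site call rate is at least `call_rate_min`;
#' records with call rate exactly at the threshold are kept (the filter
#' removes call rates *below* the cutoff). Input order is preserved and
#' per-filter removal counts are attached as the `"removed"` attribute
#' (structural variants are counted first, then low-call-rate SNVs).
#'
#' @param variants Variant data frame (see [read_variants_vcf()]).
#' @param call_rate_min Minimum call rate kept (default 0.90).
#' @return The filtered data frame, with attribute `removed`: a data frame
#'   of `filter`/`n` removal counts.
#' @export
apply_qc <- function(variants, call_rate_min = 0.90) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0L) {
    attr(variants, "removed") <- data.frame(
      filter = c("structural_variant", "low_call_rate"), n = c(0L, 0L))
    return(variants)
  }
  is_snv <- variants$variant_class == "SNV"
  ok_cr <- !is.na(variants$call_rate) & variants$call_rate >= call_rate_min
  keep <- is_snv & ok_cr
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(
    filter = c("structural_variant", "low_call_rate"),
    n = c(sum(!is_snv), sum(is_snv & !ok_cr)))
  out
}

#' Minor-allele-frequency filter
#'
#' Retains variants with MAF strictly greater than `maf_min` (a record at
#' exactly the threshold is dropped: the screen keeps MAF *greater than* the
#' cutoff).
#'
#' @param variants Variant data frame with a populated `maf` column.
#' @param maf_min MAF cutoff (default 0.05).
#' @return The filtered data frame.
#' @export
maf_filter <- function(variants, maf_min = 0.05) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0L) return(variants)
  if (anyNA(variants$maf)) {
    bad <- variants$id[is.na(variants$maf)]
    stop("missing MAF for record(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- variants[variants$maf > maf_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}
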