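## Bundled published summary tables used as pipeline inputs: the 15
## candidate binding-site SNPs with their flanking contexts, and the
## case-control genotype counts for the 10 SNPs that were genotyped.

#' Candidate binding-site SNP table
#'
#' The 15 SNPs that survived the published screening funnel, with 1-based
#' genomic location (GRCh37), per-site call rate, MAF, alleles, and the
#' +/- 9 bp flanking context in `LEFT[REF/ALT]RIGHT` form.
#'
#' @return Data frame with columns `chrom`, `pos` (1-based), `id`,
#'   `call_rate`, `maf`, `ref`, `alt`, `context`.
#' @export
candidate_snp_table <- function() {
  utils::read.delim(
    system.file("extdata", "nfkb_candidate_snps.tsv", package = "regsnpscreen"),
    sep = "\t", stringsAsFactors = FALSE, colClasses = c(chrom = "character"))
}

#' Case-control genotype counts for the genotyped binding-site SNPs
#'
#' Published genotype counts (control and dialysis-case groups) for the 10
#' SNPs with successful genotyping, as a list of
#' [`genotype_counts`][genotype_counts] objects keyed by SNP id. Row sums
#' fall short of the cohort sizes where genotypes were missing.
#'
#' @return Named list of `genotype_counts`.
#' @examples
#' gc <- esrd_genotype_counts()[["rs9395890"]]
#' odds_ratio(build_model_tables(gc)$recessive)
#' @export
esrd_genotype_counts <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "esrd_genotype_counts.tsv", package = "regsnpscreen"),
    sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    genotype_counts(
      r$snp,
      control = c(r$control_hom_ref, r$control_het, r$control_hom_alt),
      case = c(r$case_hom_ref, r$case_het, r$case_hom_alt),
      genotypes = c(r$hom_ref_genotype, r$het_genotype, r$hom_alt_genotype))
  })
  names(out) <- tab$snp
  out
}

#' Embed the candidate-SNP contexts as a miniature genome
#'
#' Builds one contig per candidate SNP containing the 19-base context with
#' the reference allele substituted at the centre, together with the
#' corresponding variant table (0-based positions). Useful for exercising
#' the scanner and the context/effect machinery on published sequence.
#'
#' @param flank_pad Extra random-free padding of `A`s either side (default
#'   0: contigs are exactly the 19-mers).
#' @return List with `genome` (named character vector, one contig per SNP)
#'   and `variants` (data frame `contig`, `pos`, `id`, `ref`, `alt`).
#' @export
candidate_context_genome <- function(flank_pad = 0L) {
  tab <- candidate_snp_table()
  pad <- strrep("A", flank_pad)
  parse_ctx <- function(ctx) {
    m <- regmatches(ctx, regexec("^([ACGT]*)\\[([ACGT])/([ACGT])\\]([ACGT]*)$", ctx))[[1]]
    if (length(m) != 5L) stop("unparseable context: ", ctx)
    m[-1]
  }
  parts <- lapply(tab$context, parse_ctx)
  genome <- vapply(parts, function(p) paste0(pad, p[1], p[2], p[4], pad),
                   character(1))
  names(genome) <- tab$id
  variants <- data.frame(
    contig = tab$id,
    pos = flank_pad + vapply(parts, function(p) nchar(p[1]), numeric(1)),
    id = tab$id,
    ref = vapply(parts, `[`, character(1), 2L),
    alt = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE)
  list(genome = genome, variants = variants)
}
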