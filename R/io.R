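## Readers and writers for the pipeline's on-disk formats: FASTA (reference),
## VCF (variants with CR/MAF INFO keys), BED3+name (peaks), TSV (subjects,
## qPCR plate).

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of contig sequences (names truncated at the
#'   first whitespace, as is conventional for sequence identifiers).
#' @export
read_reference_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  as.character(dss)
}

#' Write a reference genome to FASTA
#'
#' @param genome Named character vector of contigs or `DNAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(genome, path) {
  genome <- .as_contig_vector(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read variants from VCF
#'
#' Parses a VCF (v4.x) into the package's variant table. The 1-based VCF
#' `POS` is converted to the internal 0-based convention here, exactly once;
#' every downstream coordinate is 0-based half-open. Call rate and MAF are
#' taken from the `CR` and `MAF` INFO keys when present (`NA` otherwise),
#' and the SNV/INDEL class is recomputed from the alleles at parse time.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return Data frame with columns `contig`, `pos` (0-based), `id`, `ref`,
#'   `alt`, `variant_class`, `call_rate`, `maf`.
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(contig = character(0), pos = integer(0), id = character(0),
                      ref = character(0), alt = character(0),
                      variant_class = character(0), call_rate = numeric(0),
                      maf = numeric(0), stringsAsFactors = FALSE))
  }
  cr <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "CR")))
  maf <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MAF")))
  data.frame(
    contig = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,   # 1-based VCF -> 0-based internal
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT,
    variant_class = mapply(classify_variant, fix$REF, fix$ALT, USE.NAMES = FALSE),
    call_rate = cr,
    maf = maf,
    stringsAsFactors = FALSE
  )
}

#' Write a variant table to VCF
#'
#' Emits a minimal sites-only VCF v4.2 with `CR` (call rate), `MAF` and
#' `VC` (variant class) INFO keys; internal 0-based positions become 1-based
#' `POS`.
#'
#' @param variants Variant data frame.
#' @param path Output file.
#' @param genome Optional named contig vector used to emit `##contig` header
#'   lines with lengths.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=regsnpscreen",
    '##INFO=<ID=CR,Number=1,Type=Float,Description="Per-site call rate">',
    '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency">',
    '##INFO=<ID=VC,Number=1,Type=String,Description="Variant class (SNV/INDEL)">'
  )
  if (!is.null(genome)) {
    genome <- .as_contig_vector(genome)
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(genome), nchar(genome)))
  }
  header <- c(header,
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  body <- if (nrow(variants) == 0L) character(0) else {
    info <- sprintf("CR=%s;MAF=%s;VC=%s",
                    formatC(variants$call_rate, format = "fg", digits = 6),
                    formatC(variants$maf, format = "fg", digits = 6),
                    variants$variant_class)
    paste(variants$contig, variants$pos + 1L, variants$id, variants$ref,
          variants$alt, ".", ".", info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a subject-level genotype/phenotype table
#'
#' Expects the tab-separated schema written by [write_simulation()]:
#' `id`, `group` (`"control"`/`"case"`), `genotype`, `sex`, `age`, `bmi`,
#' `htn`, `dm`, `egfr`. Missing genotypes may be empty or `NA`.
#'
#' @param path TSV file.
#' @return Data frame of subjects.
#' @export
read_subjects <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Read a ChIP-qPCR Ct table
#'
#' Tab-separated columns `sample`, `genotype`, `ct_ip`, `ct_input`,
#' `input_fraction`.
#'
#' @param path TSV file.
#' @return Data frame of measurements.
#' @export
read_qpcr <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
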