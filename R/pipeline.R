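## Orchestration of the screening funnel and the downstream statistics.

## Accept either a path or an already-loaded object.
.load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file does not exist: ", x)
    reader(x)
  } else x
}

#' Run the regulatory-SNP screening funnel
#'
#' Executes the three screening stages in order: (1) structural-variant and
#' call-rate QC, (2) degenerate motif scan with per-allele site-effect
#' classification and a minor-allele-frequency filter, (3) confirmation of
#' motif-overlapping variants against ChIP-seq peaks. A variant counts as
#' "on the binding site" when it is contained in a reference-allele
#' occurrence (effect preserved/destroyed) or its alternate allele creates
#' a covering occurrence. Candidates and per-stage funnel counts are
#' returned; counts are non-increasing through the funnel.
#'
#' @param fasta Reference: FASTA path, named character vector or
#'   `DNAStringSet`.
#' @param vcf Variants: VCF path or variant data frame.
#' @param bed Peaks: BED path or peak data frame; `NULL` skips the peak
#'   stage (reported in the funnel).
#' @param consensus Degenerate consensus (default `"GGGRNNYYCC"`).
#' @param call_rate_min,maf_min QC thresholds (defaults 0.90, 0.05).
#' @param window Proximity window in bases for the nearest-occurrence
#'   annotation (default 500000).
#' @param snp_overlap Peak semantics: `FALSE` (default) requires the motif
#'   occurrence to overlap a peak, `TRUE` only the variant point.
#' @param out_dir Optional directory for `candidates.tsv`, `funnel.tsv` and
#'   `occurrences.bed`.
#' @return List of class `"funnel_report"`: `funnel` (stage/count data
#'   frame), `candidates` (annotated data frame), `occurrences` (genome-wide
#'   motif scan), `peak_stage_run` flag.
#' @export
run_screen <- function(fasta, vcf, bed = NULL, consensus = "GGGRNNYYCC",
                       call_rate_min = 0.90, maf_min = 0.05,
                       window = 500000L, snp_overlap = FALSE, out_dir = NULL) {
  if (is.character(fasta) && length(fasta) == 1L && !file.exists(fasta)) {
    stop("input file does not exist: ", fasta)
  }
  if (is.character(vcf) && length(vcf) == 1L && !file.exists(vcf)) {
    stop("input file does not exist: ", vcf)
  }
  if (!is.null(bed) && is.character(bed) && length(bed) == 1L && !file.exists(bed)) {
    stop("input file does not exist: ", bed)
  }
  genome <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    read_reference_fasta(fasta)
  } else .as_contig_vector(fasta)
  variants <- .load_input(vcf, read_variants_vcf)
  peaks <- if (is.null(bed)) NULL else .load_input(bed, read_peaks)
  pattern <- compile_pattern(consensus)

  n_input <- nrow(variants)
  qc <- apply_qc(variants, call_rate_min = call_rate_min)
  occurrences <- scan_motifs(genome, pattern)
  near <- snps_near_occurrences(qc, occurrences, window = window)

  if (nrow(qc) > 0L) {
    effects <- lapply(seq_len(nrow(qc)), function(i) {
      classify_allele_effect(qc[i, c("contig", "pos", "ref", "alt")],
                             genome, pattern)
    })
    qc$effect <- vapply(effects, `[[`, character(1), "effect")
    qc$cov_start <- vapply(effects, function(e) as.integer(e$cov_start), integer(1))
    qc$cov_end <- vapply(effects, function(e) as.integer(e$cov_end), integer(1))
  } else {
    qc$effect <- character(0)
    qc$cov_start <- integer(0)
    qc$cov_end <- integer(0)
  }
  on_site <- qc[qc$effect != "NO_SITE", , drop = FALSE]
  after_maf <- maf_filter(on_site, maf_min = maf_min)

  peak_stage_run <- !is.null(peaks)
  if (peak_stage_run) {
    candidates <- confirm_candidates(after_maf, peaks, snp_overlap = snp_overlap)
  } else {
    candidates <- after_maf
    candidates$peaks <- NA_character_
  }
  if (nrow(candidates) > 0L) {
    candidates$context <- vapply(seq_len(nrow(candidates)), function(i) {
      context_string(candidates[i, c("contig", "pos", "ref", "alt")],
                     genome)$context_string
    }, character(1))
  } else {
    candidates$context <- character(0)
  }
  funnel <- data.frame(
    stage = c("input", "snv_callrate_qc", "within_window", "on_binding_site",
              "maf_filter", "peak_confirmed"),
    n = c(n_input, nrow(qc), nrow(near), nrow(on_site), nrow(after_maf),
          if (peak_stage_run) nrow(candidates) else NA_integer_),
    stringsAsFactors = FALSE)
  report <- structure(
    list(funnel = funnel, candidates = candidates, occurrences = occurrences,
         peak_stage_run = peak_stage_run),
    class = "funnel_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(funnel, file.path(out_dir, "funnel.tsv"))
    .write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
    write_peaks_bed(occurrences, file.path(out_dir, "occurrences.bed"))
  }
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-16s %s\n", x$funnel$stage[i],
                ifelse(is.na(x$funnel$n[i]), "(skipped)", x$funnel$n[i])))
  }
  invisible(x)
}

#' Run the case-control association battery
#'
#' For each requested genetic model: genotype counts, crude odds ratio with
#' Wald CI and Pearson chi-square p, and (optionally) the covariate-adjusted
#' logistic estimate. Also reports the genotype-distribution chi-square and
#' the Hardy-Weinberg p in controls.
#'
#' @param subjects Subject TSV path or data frame (see [read_subjects()]).
#' @param snp_col Genotype column name (default `"genotype"`).
#' @param models Subset of `c("allele", "dominant", "recessive")`.
#' @param covariates Covariates for the adjusted fit; `character(0)` skips
#'   adjustment.
#' @param risk_allele Exposure allele of the dominant/recessive dichotomies
#'   (default: minor allele in controls). The risk allele of a genetic
#'   model need not be the minor one.
#' @param hwe_group `"control"` (default, standard practice) or `"all"`.
#' @param out_dir Optional directory for `association.tsv`.
#' @return List: `counts` (genotype_counts), `genotype_p`, `hwe`, and
#'   `results` -- a data frame with one row per model (crude and adjusted
#'   OR/CI/p columns).
#' @export
run_assoc <- function(subjects, snp_col = "genotype",
                      models = c("allele", "dominant", "recessive"),
                      covariates = c("sex", "age", "bmi", "htn", "dm"),
                      risk_allele = NULL,
                      hwe_group = c("control", "all"), out_dir = NULL) {
  hwe_group <- match.arg(hwe_group)
  subjects <- .load_input(subjects, read_subjects)
  models <- match.arg(models, several.ok = TRUE)
  gc <- genotype_counts_from_subjects(subjects, snp_col = snp_col,
                                      risk_allele = risk_allele)
  tables <- build_model_tables(gc)
  hwe_counts <- if (hwe_group == "control") gc$counts["control", ] else colSums(gc$counts)
  hwe <- hwe_test(hwe_counts)
  gp <- genotype_chisq(gc)$p.value
  coding_of <- c(allele = "additive", dominant = "dominant",
                 recessive = "recessive")
  rows <- lapply(models, function(m) {
    crude <- odds_ratio(tables[[m]])
    row <- data.frame(snp = gc$snp, model = m,
                      crude_or = crude$or, crude_lo = crude$ci[1],
                      crude_hi = crude$ci[2], crude_p = crude$p,
                      stringsAsFactors = FALSE)
    if (length(covariates) > 0L) {
      adj <- adjusted_logistic(subjects, snp_col = snp_col,
                               coding = coding_of[[m]],
                               covariates = covariates,
                               risk_allele = risk_allele)
      row$adj_or <- adj$or[1]
      row$adj_lo <- adj$ci[1]
      row$adj_hi <- if (is.matrix(adj$ci)) adj$ci[1, 2] else adj$ci[2]
      row$adj_p <- adj$p[1]
    }
    row
  })
  results <- do.call(rbind, rows)
  results$genotype_p <- gp
  results$hwe_p <- hwe$p
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(results, file.path(out_dir, "association.tsv"))
  }
  list(counts = gc, tables = tables, genotype_p = gp, hwe = hwe,
       results = results)
}

#' Run ChIP-qPCR quantification
#'
#' Per-sample percent-input, per-genotype group summaries, classical
#' one-way ANOVA, and the enrichment comparison (ratio and difference)
#' between the highest- and lowest-mean genotype groups.
#'
#' @param qpcr Ct table path or data frame (see [read_qpcr()]).
#' @param group_col Grouping column (default `"genotype"`).
#' @param out_dir Optional directory for `quantification.tsv` and
#'   `quantification.json`.
#' @return List: `samples` (with `percent_input` column), `summary`
#'   (group mean/SEM/n), `anova` (F, df, p), `enrichment` (ratio and
#'   difference, plus which groups were compared).
#' @export
run_chip <- function(qpcr, group_col = "genotype", out_dir = NULL) {
  qpcr <- .load_input(qpcr, read_qpcr)
  stopifnot(all(c("ct_ip", "ct_input", "input_fraction", group_col) %in% names(qpcr)))
  qpcr$percent_input <- percent_input(qpcr$ct_ip, qpcr$ct_input,
                                      qpcr$input_fraction)
  summ <- group_summary(qpcr$percent_input, qpcr[[group_col]])
  an <- anova_oneway(qpcr$percent_input, qpcr[[group_col]])
  hi <- summ$group[which.max(summ$mean)]
  lo <- summ$group[which.min(summ$mean)]
  enr <- enrichment_ratio(summ$mean[summ$group == hi],
                          summ$mean[summ$group == lo])
  enr$numerator_group <- hi
  enr$denominator_group <- lo
  out <- list(samples = qpcr, summary = summ, anova = an, enrichment = enr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(qpcr, file.path(out_dir, "quantification.tsv"))
    jsonlite::write_json(list(summary = summ, anova = an, enrichment = enr),
                         file.path(out_dir, "quantification.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
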