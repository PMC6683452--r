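# The generator is the test bed for the whole pipeline: determinism,
# planted ground truth recovered with zero false negatives in noise-free
# settings, and statistical calibration of the planted cohort effect.

noise_free_config <- function(seed, peak_coverage = 1.0, ...) {
  simulation_config(seed = seed, genome_length = 30000L, n_contigs = 3L,
                    n_planted_motifs = 10L, n_variants = 60L,
                    n_motif_variants = 10L, callrate_beta_params = 0.99,
                    maf_range = c(0.10, 0.45), peak_coverage = peak_coverage,
                    ...)
}

test_that("identical configurations write byte-identical files", {
  cfg <- noise_free_config(31)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  p1 <- write_simulation(simulate_inputs(cfg), d1)
  p2 <- write_simulation(simulate_inputs(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  }
  # and a different seed changes the reference
  p3 <- write_simulation(simulate_inputs(noise_free_config(32)),
                         file.path(tempdir(), "simC"))
  expect_false(identical(readLines(p1$fasta), readLines(p3$fasta)))
})

test_that("every planted motif is recovered by the scanner", {
  cfg <- noise_free_config(41)
  ref <- gen_reference(cfg)
  expect_equal(nrow(ref$planted), 10L)
  occ <- scan_motifs(ref$genome, cfg$consensus)
  expect_gte(nrow(occ), 10L)
  key <- function(df) paste(df$contig, df$start, df$strand)
  expect_true(all(key(ref$planted) %in% key(occ)))
  # planted instances actually sit in the sequence
  for (i in seq_len(nrow(ref$planted))) {
    m <- ref$planted[i, ]
    expect_equal(substr(ref$genome[[m$contig]], m$start + 1, m$end),
                 m$instance)
  }
})

test_that("with no planted motifs only chance matches remain, at the expected density", {
  cfg <- simulation_config(seed = 51, genome_length = 200000L, n_contigs = 1L,
                           n_planted_motifs = 0L, n_variants = 0L,
                           n_motif_variants = 0L)
  ref <- gen_reference(cfg)
  expect_equal(nrow(ref$planted), 0L)
  occ <- scan_motifs(ref$genome, cfg$consensus)
  expected <- 2 * (200000 - 9) / 8192
  expect_lt(abs(nrow(occ) - expected), 6 * sqrt(expected))
})

test_that("an over-packed genome fails with a sizing error", {
  expect_error(simulation_config(seed = 1, genome_length = 50L),
               "10x the consensus")
  cfg <- simulation_config(seed = 1, genome_length = 120L, n_contigs = 1L,
                           n_planted_motifs = 12L, n_variants = 0L,
                           n_motif_variants = 0L)
  expect_error(gen_reference(cfg), "too short")
})

test_that("variant ground-truth labels are consistent and oracle-verified", {
  cfg <- noise_free_config(61, motif_destroy_fraction = 0.5)
  ref <- gen_reference(cfg)
  v <- gen_variants(cfg, ref)
  expect_equal(nrow(v), 60L)
  expect_equal(sum(v$variant_class == "INDEL"), round(0.194 * 60))
  expect_equal(sum(v$inside_motif), 10L)
  expect_equal(sum(v$destroys_site), 5L)

  occ <- scan_motifs(ref$genome, cfg$consensus)
  snvs <- v[v$variant_class == "SNV", ]
  # containment recovery: inside_motif labels match the containment stage
  inside <- snps_in_occurrences(snvs, occ)
  expect_setequal(inside$id, snvs$id[snvs$inside_motif])
  # destroys_site labels verified by brute-force rescans of both alleles
  for (i in which(snvs$destroys_site)) {
    s <- ref$genome[[snvs$contig[i]]]
    sub <- function(allele) paste0(substr(s, 1, snvs$pos[i]), allele,
                                   substr(s, snvs$pos[i] + 2, nchar(s)))
    win <- function(allele) {
      o <- oracle_scan(substr(sub(allele), max(1, snvs$pos[i] - 8),
                              min(nchar(s), snvs$pos[i] + 10)))
      nrow(o)
    }
    expect_gt(win(snvs$ref[i]), 0)
    expect_equal(win(snvs$alt[i]), 0)
  }
  # decoys never touch or create a site
  expect_true(all(snvs$effect_truth[!snvs$inside_motif] == "NO_SITE"))
})

test_that("point-mass call rate above the cutoff keeps all generated SNVs", {
  cfg <- simulation_config(seed = 71, genome_length = 20000L,
                           n_variants = 100L, n_motif_variants = 5L,
                           indel_fraction = 0, callrate_beta_params = 0.95)
  ref <- gen_reference(cfg)
  v <- gen_variants(cfg, ref)
  expect_true(all(v$variant_class == "SNV"))
  expect_equal(nrow(apply_qc(v)), 100L)
})

test_that("peak coverage is exact over planted motifs", {
  cfg <- noise_free_config(81, peak_coverage = 0.6, n_decoy_peaks = 4L)
  ref <- gen_reference(cfg)
  pk <- gen_peaks(cfg, ref)
  expect_equal(length(pk$covered), 6L)   # 0.6 of 10 motifs
  for (i in pk$covered) {
    m <- ref$planted[i, ]
    p <- pk$peaks[pk$peaks$contig == m$contig, ]
    expect_true(oracle_overlaps_any(m$start, m$end, p$start, p$end))
  }
  # full coverage: every planted motif supported
  pk_full <- gen_peaks(noise_free_config(81), ref)
  expect_setequal(pk_full$covered, seq_len(10))
  # zero coverage, no decoys: nothing to intersect
  pk_none <- gen_peaks(noise_free_config(81, peak_coverage = 0,
                                         n_decoy_peaks = 0L), ref)
  expect_equal(nrow(pk_none$peaks), 0L)
})

test_that("cohort genotype distributions and eGFR respect the group definitions", {
  cfg <- simulation_config(seed = 91, n_cases = 500L, n_controls = 500L,
                           cohort_call_rate = 0.95)
  s <- gen_cohort(cfg)
  expect_equal(nrow(s), 1000L)
  expect_true(all(s$egfr[s$group == "control"] >= 60))
  expect_true(all(s$egfr[s$group == "case"] <= 15 & s$egfr[s$group == "case"] > 0))
  miss <- mean(is.na(s$genotype))
  expect_lt(abs(miss - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  expect_error(simulation_config(seed = 1, planted_or = 0), "positive")
  expect_error(simulation_config(
    seed = 1, planted_snp_control_genotype_freqs = c(0.5, 0.4, 0.2)),
    "summing to 1")
})

test_that("a null planted effect is rejected at the nominal rate", {
  rejections <- vapply(1:500, function(k) {
    cfg <- simulation_config(seed = 10000 + k, n_cases = 400L,
                             n_controls = 400L, planted_or = 1.0,
                             cohort_call_rate = 1)
    gc <- genotype_counts_from_subjects(gen_cohort(cfg), risk_allele = "T")
    odds_ratio(build_model_tables(gc)$recessive)$p < 0.05
  }, logical(1))
  tol <- 3 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rejections) - 0.05), tol)
})

test_that("qPCR generator honours a zero-noise setting and input checks", {
  plate <- gen_qpcr(group_sem = c(0, 0, 0), seed = 3)
  s <- group_summary(percent_input(plate$ct_ip, plate$ct_input,
                                   plate$input_fraction), plate$genotype)
  expect_equal(s$mean[match(c("GG", "GT", "TT"), s$group)],
               c(1.71, 2.81, 3.20), tolerance = 1e-9)
  expect_error(gen_qpcr(group_means = c(GG = -1, GT = 2, TT = 3)), "positive")
  expect_error(gen_qpcr(n_per_group = 1), "at least 2")
})
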