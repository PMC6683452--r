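## Seeded synthetic-data generator: emits every input the screening and
## association pipeline consumes (reference FASTA, variant VCF, peak BED,
## subject table, qPCR plate) with planted, machine-readable ground truth.
##
## Defaults are the study conditions the pipeline is meant to emulate: a
## cohort of 847 dialysis cases / 846 controls, control genotype
## frequencies (0.181, 0.495, 0.324) at the index SNP with a planted
## recessive odds ratio of 1.31, an indel fraction of 0.194 among called
## variants, call-rate heterogeneity straddling the 0.90 QC cutoff, and
## qPCR percent-input group means (1.71, 2.81, 3.20).

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## Evaluate expr under a local seed, leaving the caller's RNG untouched.
## The seed promise is forced first: if it is itself a random draw, that
## draw must advance the caller's RNG, not be rolled back with it.
.with_seed <- function(seed, expr) {
  force(seed)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}

.default_covariates <- function() {
  list(
    control = list(sex_male_p = 0.446, age_mean = 73.50, age_sd = 7.21,
                   bmi_mean = 24.22, bmi_sd = 3.37, htn_p = 0.427,
                   dm_p = 0.125, egfr_mean = 93.81, egfr_sd = 23.76),
    case = list(sex_male_p = 0.508, age_mean = 71.84, age_sd = 12.93,
                bmi_mean = 24.66, bmi_sd = 4.80, htn_p = 0.813,
                dm_p = 0.803, egfr_mean = 5.73, egfr_sd = 2.45)
  )
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' same configuration (including `seed`) always produces byte-identical
#' outputs.
#'
#' @param seed Integer seed driving all randomness (keep below 2^31 - 16;
#'   stage-specific sub-seeds are small offsets of it).
#' @param genome_length Total reference length in bases, split across
#'   `n_contigs` near-equal contigs.
#' @param n_contigs Number of contigs.
#' @param n_planted_motifs Non-overlapping concrete instantiations of the
#'   consensus planted at random positions and strands.
#' @param n_variants Total variant records to emit.
#' @param n_motif_variants How many of the variants are SNVs placed inside
#'   planted motif occurrences (the rest are decoys kept clear of any
#'   occurrence).
#' @param motif_destroy_fraction Fraction of motif variants targeted at
#'   consensus-critical offsets so the alternate allele abolishes the site;
#'   the rest hit fully degenerate (N) offsets and preserve it.
#' @param indel_fraction Fraction of all variants that are insertion/
#'   deletion class (default 0.194, the structural fraction of a
#'   whole-genome call set of ~59M variants of which ~11.4M are structural).
#' @param callrate_beta_params Either a single value (point mass) or
#'   `c(a, b)` of a Beta law truncated to [0.5, 1] for per-site call rates.
#'   The default `c(30, 2)` puts roughly a quarter of sites below the 0.90
#'   cutoff.
#' @param maf_range Interval within [0, 0.5] for uniform MAF draws (equal
#'   endpoints give a point mass).
#' @param peak_coverage Fraction of planted motifs covered by a ChIP-seq
#'   peak (`round(coverage * n_planted_motifs)` motifs are covered).
#' @param n_decoy_peaks Peaks overlapping no motif occurrence.
#' @param n_cases,n_controls Cohort group sizes.
#' @param planted_snp_control_genotype_freqs Control genotype frequencies
#'   (major hom, het, minor hom) at the planted SNP; must sum to 1.
#' @param planted_or Recessive-model odds ratio planted on the minor
#'   homozygote vs carrier dichotomy (> 0).
#' @param cohort_call_rate Per-subject probability of a non-missing
#'   genotype (default 0.993).
#' @param covariate_means_by_group Per-group covariate parameters (see
#'   source for the schema); defaults emulate an elderly dialysis
#'   case-control cohort.
#' @param consensus Degenerate consensus to plant and scan (default the
#'   NF-kB motif `"GGGRNNYYCC"`).
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed,
                              genome_length = 60000L,
                              n_contigs = 3L,
                              n_planted_motifs = 15L,
                              n_variants = 300L,
                              n_motif_variants = 15L,
                              motif_destroy_fraction = 0.5,
                              indel_fraction = 0.194,
                              callrate_beta_params = c(30, 2),
                              maf_range = c(0, 0.5),
                              peak_coverage = 0.6,
                              n_decoy_peaks = 10L,
                              n_cases = 847L,
                              n_controls = 846L,
                              planted_snp_control_genotype_freqs = c(0.181, 0.495, 0.324),
                              planted_or = 1.31,
                              cohort_call_rate = 0.993,
                              covariate_means_by_group = .default_covariates(),
                              consensus = "GGGRNNYYCC") {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == floor(seed),
            seed >= 0, seed < 2^31 - 16)
  f <- planted_snp_control_genotype_freqs
  if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    stop("planted_snp_control_genotype_freqs must be a 3-vector summing to 1 (tolerance 1e-9)")
  }
  if (planted_or <= 0) stop("planted_or must be positive")
  counts <- c(genome_length, n_contigs, n_planted_motifs, n_variants,
              n_motif_variants, n_decoy_peaks, n_cases, n_controls)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (indel_fraction < 0 || indel_fraction > 1) stop("indel_fraction must be in [0, 1]")
  if (peak_coverage < 0 || peak_coverage > 1) stop("peak_coverage must be in [0, 1]")
  if (!length(callrate_beta_params) %in% 1:2 || any(callrate_beta_params <= 0)) {
    stop("callrate_beta_params must be a point mass or a pair of positive reals")
  }
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] < 0 || maf_range[2] > 0.5) {
    stop("maf_range must be an interval within [0, 0.5]")
  }
  if (cohort_call_rate <= 0 || cohort_call_rate > 1) {
    stop("cohort_call_rate must be in (0, 1]")
  }
  pattern <- compile_pattern(consensus)
  if (genome_length < 10L * pattern$length) {
    stop("genome_length must be at least 10x the consensus length")
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_contigs = as.integer(n_contigs),
    n_planted_motifs = as.integer(n_planted_motifs),
    n_variants = as.integer(n_variants),
    n_motif_variants = as.integer(min(n_motif_variants, n_variants)),
    motif_destroy_fraction = motif_destroy_fraction,
    indel_fraction = indel_fraction,
    callrate_beta_params = callrate_beta_params,
    maf_range = maf_range,
    peak_coverage = peak_coverage,
    n_decoy_peaks = as.integer(n_decoy_peaks),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    planted_snp_control_genotype_freqs = f,
    planted_or = planted_or,
    cohort_call_rate = cohort_call_rate,
    covariate_means_by_group = covariate_means_by_group,
    consensus = pattern$consensus
  ), class = "simulation_config")
}

#' Generate a reference genome with planted motif occurrences
#'
#' Contigs of iid-uniform bases with exactly `n_planted_motifs`
#' non-overlapping concrete instantiations of the consensus (random strand,
#' random resolution of degenerate positions). Chance occurrences of the
#' consensus arise on top of the planted ones at the expected density of
#' about 2/8192 per offset for the NF-kB motif.
#'
#' @param config A [`simulation_config`][simulation_config].
#' @return List with `genome` (named character vector) and `planted` (data
#'   frame: `contig`, `start`, `end`, `strand`, `instance` -- the
#'   forward-strand sequence inserted).
#' @export
gen_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pattern <- compile_pattern(config$consensus)
  L <- pattern$length
  .with_seed(config$seed, {
    base_len <- config$genome_length %/% config$n_contigs
    lens <- rep(base_len, config$n_contigs)
    lens[1] <- lens[1] + config$genome_length %% config$n_contigs
    if (any(lens < L) && config$n_planted_motifs > 0L) {
      stop("contigs shorter than the consensus: genome too short")
    }
    contigs <- lapply(lens, function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE))
    names(contigs) <- sprintf("ctg%d", seq_along(contigs))

    planted <- data.frame(contig = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          instance = character(0), stringsAsFactors = FALSE)
    occupied <- lapply(contigs, function(x) integer(0))
    attempts <- 0L
    max_attempts <- 1000L * max(1L, config$n_planted_motifs)
    while (nrow(planted) < config$n_planted_motifs) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("genome too short to place ", config$n_planted_motifs,
             " non-overlapping motifs")
      }
      ci <- sample.int(config$n_contigs, 1L)
      if (lens[ci] < L) next
      start <- sample.int(lens[ci] - L + 1L, 1L) - 1L  # 0-based
      span <- (start + 1L):(start + L)
      if (any(span %in% occupied[[ci]])) next
      strand <- sample(c("+", "-"), 1L)
      inst <- vapply(pattern$base_sets,
                     function(s) s[sample.int(length(s), 1L)], character(1))
      inst <- paste(inst, collapse = "")
      fwd <- if (strand == "+") inst else iupac_revcomp(inst)
      contigs[[ci]][span] <- strsplit(fwd, "", fixed = TRUE)[[1]]
      occupied[[ci]] <- c(occupied[[ci]], span)
      planted <- rbind(planted, data.frame(
        contig = names(contigs)[ci], start = start, end = start + L,
        strand = strand, instance = fwd, stringsAsFactors = FALSE))
    }
    genome <- vapply(contigs, paste, character(1), collapse = "")
    planted <- planted[order(planted$contig, planted$start), , drop = FALSE]
    rownames(planted) <- NULL
    list(genome = genome, planted = planted)
  })
}

.draw_callrate <- function(n, params) {
  if (length(params) == 1L) return(rep(params, n))
  a <- params[1]; b <- params[2]
  lo <- stats::pbeta(0.5, a, b)
  stats::qbeta(stats::runif(n, lo, 1), a, b)
}

.draw_maf <- function(n, range) {
  if (range[1] == range[2]) return(rep(range[1], n))
  stats::runif(n, range[1], range[2])
}

#' Generate a variant set over a simulated reference
#'
#' Emits `n_variants` records: `n_motif_variants` SNVs inside planted motif
#' occurrences (a `motif_destroy_fraction` of them at consensus-critical
#' offsets where the alternate allele abolishes the covering site, the rest
#' at fully degenerate offsets where it is preserved), plus decoy SNVs and
#' indels rejection-sampled to neither touch nor create any motif
#' occurrence. Call rates follow the configured (possibly truncated-Beta)
#' law and MAFs are uniform on `maf_range`. Ground-truth labels
#' (`inside_motif`, `destroys_site`, `effect_truth`) ride along as columns;
#' they are not written to VCF.
#'
#' @param config A [`simulation_config`][simulation_config].
#' @param reference Output of [gen_reference()] (list with `genome` and
#'   `planted`).
#' @return Variant data frame sorted by (contig, pos), with ground-truth
#'   columns appended.
#' @export
gen_variants <- function(config, reference) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- reference$genome
  planted <- reference$planted
  pattern <- compile_pattern(config$consensus)
  L <- pattern$length
  occ_all <- scan_motifs(genome, pattern)

  .with_seed(config$seed + 1L, {
    n_motif <- min(config$n_motif_variants, nrow(planted), config$n_variants)
    n_destroy <- round(config$motif_destroy_fraction * n_motif)
    motif_idx <- if (nrow(planted) > 0L) sample.int(nrow(planted)) else integer(0)
    critical <- which(lengths(pattern$base_sets) < 4L) - 1L  # 0-based offsets
    degenerate <- which(lengths(pattern$base_sets) == 4L) - 1L

    motif_rows <- list()
    for (k in seq_len(n_motif)) {
      m <- planted[motif_idx[k], ]
      want_destroy <- k <= n_destroy
      offsets <- if (want_destroy) critical else degenerate
      if (length(offsets) == 0L) offsets <- 0:(L - 1L)
      placed <- FALSE
      for (attempt in seq_len(60L)) {
        off <- offsets[sample.int(length(offsets), 1L)]
        pos <- if (m$strand == "+") m$start + off else m$start + (L - 1L - off)
        ref <- substr(genome[[m$contig]], pos + 1L, pos + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        eff <- classify_allele_effect(
          list(contig = m$contig, pos = pos, ref = ref, alt = alt),
          genome, pattern)
        ok <- if (want_destroy) eff$effect == "SITE_DESTROYED"
              else eff$effect == "SITE_PRESERVED"
        if (ok) {
          motif_rows[[k]] <- data.frame(
            contig = m$contig, pos = pos, ref = ref, alt = alt,
            variant_class = "SNV", inside_motif = TRUE,
            destroys_site = eff$effect == "SITE_DESTROYED",
            effect_truth = eff$effect, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place a ", if (want_destroy) "site-destroying"
             else "site-preserving", " variant in planted motif ", motif_idx[k])
      }
    }
    motif_df <- if (length(motif_rows)) do.call(rbind, motif_rows) else NULL

    ## positions free of any occurrence (planted or chance), per contig
    free <- lapply(names(genome), function(ctg) {
      n <- nchar(genome[[ctg]])
      occupied <- logical(n)
      occ <- occ_all[occ_all$contig == ctg, , drop = FALSE]
      for (i in seq_len(nrow(occ))) {
        occupied[(occ$start[i] + 1L):occ$end[i]] <- TRUE
      }
      which(!occupied) - 1L
    })
    names(free) <- names(genome)
    free_pool <- data.frame(
      contig = rep(names(free), lengths(free)),
      pos = unlist(free, use.names = FALSE), stringsAsFactors = FALSE)

    n_decoy <- config$n_variants - n_motif
    n_indel <- round(config$indel_fraction * config$n_variants)
    if (n_indel > n_decoy) {
      stop("indel_fraction too high: indels exceed available decoy slots")
    }
    n_decoy_snv <- n_decoy - n_indel
    if (nrow(free_pool) < n_decoy * 2L) {
      stop("genome too short for the requested number of decoy variants")
    }
    pool_order <- sample.int(nrow(free_pool))
    pool_ptr <- 0L
    next_free <- function() {
      pool_ptr <<- pool_ptr + 1L
      if (pool_ptr > length(pool_order)) stop("variant position pool exhausted")
      free_pool[pool_order[pool_ptr], ]
    }

    decoy_rows <- list()
    for (k in seq_len(n_decoy_snv)) {
      repeat {
        p <- next_free()
        ref <- substr(genome[[p$contig]], p$pos + 1L, p$pos + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        eff <- classify_allele_effect(
          list(contig = p$contig, pos = p$pos, ref = ref, alt = alt),
          genome, pattern)
        if (eff$effect == "NO_SITE") {
          decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
            contig = p$contig, pos = p$pos, ref = ref, alt = alt,
            variant_class = "SNV", inside_motif = FALSE, destroys_site = FALSE,
            effect_truth = "NO_SITE", stringsAsFactors = FALSE)
          break
        }
      }
    }
    for (k in seq_len(n_indel)) {
      repeat {
        p <- next_free()
        clen <- nchar(genome[[p$contig]])
        if (p$pos >= clen - 1L) next
        base <- substr(genome[[p$contig]], p$pos + 1L, p$pos + 1L)
        if (stats::runif(1) < 0.5) {           # deletion
          ref <- substr(genome[[p$contig]], p$pos + 1L, p$pos + 2L)
          alt <- base
        } else {                               # insertion
          ref <- base
          alt <- paste0(base, sample(c("A", "C", "G", "T"), 1L))
        }
        decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
          contig = p$contig, pos = p$pos, ref = ref, alt = alt,
          variant_class = "INDEL", inside_motif = FALSE, destroys_site = FALSE,
          effect_truth = NA_character_, stringsAsFactors = FALSE)
        break
      }
    }
    out <- rbind(motif_df, if (length(decoy_rows)) do.call(rbind, decoy_rows))
    if (is.null(out)) {
      out <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        variant_class = character(0), inside_motif = logical(0),
                        destroys_site = logical(0), effect_truth = character(0),
                        stringsAsFactors = FALSE)
    }
    if (any(out$pos < 0L) ||
        any(out$pos >= nchar(genome[out$contig]))) {
      stop("generated variant position outside contig bounds")
    }
    out$call_rate <- .draw_callrate(nrow(out), config$callrate_beta_params)
    out$maf <- .draw_maf(nrow(out), config$maf_range)
    out <- out[order(out$contig, out$pos), , drop = FALSE]
    out$id <- sprintf("sim%04d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[, c("contig", "pos", "id", "ref", "alt", "variant_class",
            "call_rate", "maf", "inside_motif", "destroys_site",
            "effect_truth")]
  })
}

#' Generate ChIP-seq peaks over planted motifs
#'
#' Covers `round(peak_coverage * n_planted_motifs)` planted motifs with
#' peaks (random 20-200 bp padding either side, clipped to the contig),
#' plus `n_decoy_peaks` decoys overlapping no motif occurrence.
#'
#' @param config A [`simulation_config`][simulation_config].
#' @param reference Output of [gen_reference()].
#' @return List with `peaks` (data frame `contig`, `start`, `end`, `name`)
#'   and `covered` (row indices into `reference$planted` of peak-supported
#'   motifs).
#' @export
gen_peaks <- function(config, reference) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- reference$genome
  planted <- reference$planted
  pattern <- compile_pattern(config$consensus)
  occ_all <- scan_motifs(genome, pattern)
  .with_seed(config$seed + 2L, {
    n_cov <- round(config$peak_coverage * nrow(planted))
    covered <- if (nrow(planted) > 0L) sort(sample.int(nrow(planted), n_cov)) else integer(0)
    rows <- list()
    for (i in covered) {
      m <- planted[i, ]
      clen <- nchar(genome[[m$contig]])
      s <- max(0L, m$start - sample(20:200, 1L))
      e <- min(clen, m$end + sample(20:200, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = m$contig, start = s, end = e,
        name = sprintf("motif_peak_%d", i), stringsAsFactors = FALSE)
    }
    for (j in seq_len(config$n_decoy_peaks)) {
      for (attempt in seq_len(1000L)) {
        ctg <- sample(names(genome), 1L)
        clen <- nchar(genome[[ctg]])
        w <- sample(100:300, 1L)
        if (clen <= w) next
        s <- sample.int(clen - w, 1L) - 1L
        e <- s + w
        occ <- occ_all[occ_all$contig == ctg, , drop = FALSE]
        if (nrow(occ) == 0L || all(occ$end <= s | occ$start >= e)) {
          rows[[length(rows) + 1L]] <- data.frame(
            contig = ctg, start = s, end = e,
            name = sprintf("decoy_peak_%d", j), stringsAsFactors = FALSE)
          break
        }
        if (attempt == 1000L) stop("could not place decoy peak clear of motifs")
      }
    }
    peaks <- if (length(rows)) do.call(rbind, rows) else
      data.frame(contig = character(0), start = integer(0), end = integer(0),
                 name = character(0), stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$contig, peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
    list(peaks = peaks, covered = covered)
  })
}

## Truncated-normal draw by rejection within [lo, hi].
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a case-control cohort with a planted recessive effect
#'
#' Controls draw genotypes from the configured frequencies; cases draw from
#' the distribution obtained by multiplying the odds of the minor
#' homozygote (vs carrier) by `planted_or` and renormalizing -- the
#' standard retrospective-sampling construction. Covariates are drawn per
#' group, and eGFR is drawn consistently with the group definitions (cases
#' <= 15, controls >= 60 mL/min/1.73 m^2). Genotypes are set missing with
#' probability `1 - cohort_call_rate`.
#'
#' @param config A [`simulation_config`][simulation_config].
#' @return Subject data frame: `id`, `group`, `genotype` (e.g. `"TT"`,
#'   `NA` if missing), `sex` (1 = male), `age`, `bmi`, `htn`, `dm`, `egfr`.
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  f <- config$planted_snp_control_genotype_freqs
  w <- f * c(1, 1, config$planted_or)
  case_f <- w / sum(w)
  if (any(case_f < 0) || any(case_f > 1)) {
    stop("planted_or drives a case genotype frequency out of [0, 1]")
  }
  labels <- c("GG", "GT", "TT")
  cov <- config$covariate_means_by_group
  .with_seed(config$seed + 3L, {
    draw_group <- function(n, group, freqs) {
      p <- cov[[group]]
      geno <- sample(labels, n, replace = TRUE, prob = freqs)
      geno[stats::runif(n) > config$cohort_call_rate] <- NA_character_
      egfr <- if (group == "control") {
        .rtruncnorm(n, p$egfr_mean, p$egfr_sd, lo = 60)
      } else {
        .rtruncnorm(n, p$egfr_mean, p$egfr_sd, lo = 0.1, hi = 15)
      }
      data.frame(
        group = group, genotype = geno,
        sex = stats::rbinom(n, 1L, p$sex_male_p),
        age = stats::rnorm(n, p$age_mean, p$age_sd),
        bmi = stats::rnorm(n, p$bmi_mean, p$bmi_sd),
        htn = stats::rbinom(n, 1L, p$htn_p),
        dm = stats::rbinom(n, 1L, p$dm_p),
        egfr = egfr, stringsAsFactors = FALSE)
    }
    out <- rbind(draw_group(config$n_controls, "control", f),
                 draw_group(config$n_cases, "case", case_f))
    out <- cbind(id = sprintf("S%04d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate a ChIP-qPCR plate from target percent-input group means
#'
#' Draws per-sample percent-input from a normal law with the given group
#' mean and standard deviation `sem * sqrt(n)` (so the group mean has the
#' stated SEM), then back-converts to IP / input Ct pairs by inverting the
#' percent-input formula. Running [percent_input()] on the emitted Ct pairs
#' recovers the drawn values to floating-point accuracy.
#'
#' @param group_means Named positive means on the percent-input scale
#'   (default the study's measured values for GG/GT/TT).
#' @param group_sem Per-group SEMs (>= 0).
#' @param n_per_group Samples per group (>= 2).
#' @param input_fraction Input chromatin fraction (default 0.01).
#' @param seed Seed for the draws.
#' @return Data frame: `sample`, `genotype`, `ct_ip`, `ct_input`,
#'   `input_fraction`, plus the latent `percent_true` column.
#' @export
gen_qpcr <- function(group_means = c(GG = 1.71, GT = 2.81, TT = 3.20),
                     group_sem = c(GG = 0.18, GT = 0.20, TT = 0.16),
                     n_per_group = 3L, input_fraction = 0.01, seed = 1L) {
  if (any(group_means <= 0)) stop("group means must be positive")
  if (any(group_sem < 0)) stop("group SEMs must be non-negative")
  if (n_per_group < 2L) stop("n_per_group must be at least 2")
  if (is.null(names(group_means))) {
    names(group_means) <- paste0("g", seq_along(group_means))
  }
  if (length(group_sem) != length(group_means)) {
    group_sem <- rep_len(group_sem, length(group_means))
  }
  .with_seed(seed, {
    rows <- lapply(seq_along(group_means), function(i) {
      sd_i <- group_sem[i] * sqrt(n_per_group)
      pct <- .rtruncnorm(n_per_group, group_means[i], sd_i, lo = 1e-6)
      ct_input <- stats::rnorm(n_per_group, 25, 0.5)
      adjusted <- ct_input - log2(1 / input_fraction)
      ct_ip <- adjusted - log2(pct / 100)
      data.frame(
        sample = sprintf("%s_%d", names(group_means)[i], seq_len(n_per_group)),
        genotype = names(group_means)[i],
        ct_ip = ct_ip, ct_input = ct_input,
        input_fraction = input_fraction, percent_true = pct,
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate every pipeline input in one call
#'
#' Runs [gen_reference()], [gen_variants()], [gen_peaks()], [gen_cohort()]
#' and [gen_qpcr()] under stage-specific sub-seeds of `config$seed` and
#' collects the ground truth.
#'
#' @param config A [`simulation_config`][simulation_config].
#' @return List with `config`, `genome`, `planted`, `variants`, `peaks`,
#'   `covered_motifs`, `subjects`, `qpcr` and `truth` (the JSON-ready
#'   ground-truth sidecar).
#' @export
simulate_inputs <- function(config) {
  reference <- gen_reference(config)
  variants <- gen_variants(config, reference)
  pk <- gen_peaks(config, reference)
  subjects <- gen_cohort(config)
  qpcr <- gen_qpcr(seed = config$seed + 4L)
  truth <- list(
    seed = config$seed,
    consensus = config$consensus,
    planted_motifs = reference$planted,
    covered_motifs = pk$covered,
    variant_labels = variants[, c("id", "inside_motif", "destroys_site",
                                  "effect_truth")],
    planted_or = config$planted_or,
    control_genotype_freqs = config$planted_snp_control_genotype_freqs
  )
  list(config = config, genome = reference$genome,
       planted = reference$planted, variants = variants,
       peaks = pk$peaks, covered_motifs = pk$covered,
       subjects = subjects, qpcr = qpcr, truth = truth)
}

#' Write a simulation to disk in standard formats
#'
#' Emits `reference.fasta`, `variants.vcf`, `peaks.bed`, `subjects.tsv`,
#' `qpcr.tsv` and `truth.json` into `dir`. Identical configurations write
#' byte-identical files.
#'
#' @param sim Output of [simulate_inputs()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "reference.fasta"),
    vcf = file.path(dir, "variants.vcf"),
    bed = file.path(dir, "peaks.bed"),
    subjects = file.path(dir, "subjects.tsv"),
    qpcr = file.path(dir, "qpcr.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_reference_fasta(sim$genome, paths$fasta)
  write_variants_vcf(
    sim$variants[, c("contig", "pos", "id", "ref", "alt", "variant_class",
                     "call_rate", "maf")],
    paths$vcf, genome = sim$genome)
  write_peaks_bed(sim$peaks, paths$bed)
  .write_tsv(sim$subjects, paths$subjects)
  .write_tsv(sim$qpcr[, c("sample", "genotype", "ct_ip", "ct_input",
                          "input_fraction")], paths$qpcr)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(paths)
}
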