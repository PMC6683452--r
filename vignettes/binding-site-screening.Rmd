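---
title: "Screening regulatory SNPs in NF-kB binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening regulatory SNPs in NF-kB binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsnpscreen)
```

## The problem

NF-kB is the central transcription factor of the inflammatory response; its
p50-p65 heterodimer recognizes the degenerate DNA consensus
5'-GGGRNNYYCC-3' (R = A/G, Y = C/T, N = any base). A single-nucleotide
variant that falls on such a site can strengthen, weaken or abolish binding
and thereby change the expression of downstream inflammatory genes — a
mechanism of interest in chronic inflammatory conditions such as end-stage
renal disease (ESRD). `regsnpscreen` implements the full analysis path for
such *regulatory-SNP* candidates:

1. **Variant QC** — remove structural (insertion/deletion) variants and
   sites with a call rate below 90%;
2. **Motif scan** — find all consensus occurrences in a reference sequence
   on both strands, classify each variant allele's effect on covering
   sites, and keep variants with minor allele frequency above 5%;
3. **Peak intersection** — require ChIP-seq evidence that the binding site
   is actually occupied;
4. **Association** — case-control statistics on the surviving SNPs
   (Hardy-Weinberg equilibrium, genotype chi-square, allele/dominant/
   recessive odds ratios, covariate-adjusted logistic regression, power);
5. **Quantification** — ChIP-qPCR percent-input enrichment by genotype
   with one-way ANOVA.

Because the variant call set this kind of screen runs on (a national
biobank) and the individual-level cohort are not distributable, the package
ships a seeded simulator that generates every input with planted ground
truth, so the whole pipeline is testable end to end.

## Motif scanning

`compile_pattern()` resolves each IUPAC symbol into its set of allowed
bases; `scan_motifs()` reports every offset where the consensus matches,
using 0-based half-open coordinates throughout (BED convention; VCF
positions are converted once at parse time). Design choices:

* **Both strands by default.** The consensus is not its own reverse
  complement (`iupac_revcomp("GGGRNNYYCC")` is `GGRRNNYCCC`), so the two
  strands are genuinely different searches. A 10-mer can nevertheless
  satisfy both patterns at once — `GGGAAGTCCC` does — and is then reported
  twice, once per strand.
* **Exact degenerate matching, no mismatch tolerance and no
  position-weight matrix.** The screen is defined by a single literal
  consensus; scoring models are out of scope.
* **Ambiguity rule.** A reference `N` matches only the pattern symbol `N`,
  so runs of unknown sequence are never reported as binding sites.

On iid-uniform sequence the expected match density is
$(1/4)^5 (1/2)^3 = 1/8192$ per offset per strand (five fixed bases, one
two-base and two two-base degenerate positions), i.e. about 244 matches
per Mb over both strands; the test suite checks this by Monte Carlo
against a brute-force oracle matcher.

### Allele effects

`classify_allele_effect()` evaluates the window
$[pos-(L-1),\,pos+L)$ around an SNV twice — once per allele — and compares
the occurrences that *cover* the variant position: `SITE_PRESERVED`,
`SITE_DESTROYED`, `SITE_CREATED`, or `NO_SITE`. "On the binding site" is
taken as containment in a reference-allele occurrence *or* creation of a
covering occurrence by the alternate allele; the published candidate list
contains both kinds (one index SNP creates a site with its G allele), so
classifying only reference-allele containment would silently drop them.
Swapping `ref` and `alt` exchanges DESTROYED and CREATED and fixes the
other two labels, which the tests exercise as a property.

Two proximity operations are kept distinct because a screening pipeline of
this shape reports both: `snps_near_occurrences()` (distance at most
500 kb from a site, distance 0 inside it, a variant exactly at the window
edge retained) and `snps_in_occurrences()` (half-open containment). The
candidate list is fed by containment; the window count is reported in the
funnel.

## Filter semantics

The two QC thresholds are stated as inequalities, so the boundary rules
are explicit and tested: a call rate of exactly 0.90 is **kept** (the
filter removes "less than 90%"), and a MAF of exactly 0.05 is **dropped**
(the screen keeps "greater than 5%"). All non-SNV records count as
structural variants and are removed, including pure insertions. Filters
preserve input order, are idempotent, commute, and only ever shrink the
set.

## Peak intersection

`confirm_candidates()` requires at least one base of overlap between a
candidate's covering occurrence interval and a ChIP-seq peak: the evidence
requirement is about the *binding site*, not the variant point. Because
every covering occurrence contains the variant position, the union of
covering occurrences is a single interval and is stored as
`cov_start`/`cov_end`; overlap against that hull is exact. A
`snp_overlap = TRUE` switch gives point-in-peak semantics for
sensitivity analysis, since either reading of "confirmed at these
positions" is defensible.

## Association statistics

All conventions were fixed by recomputing a published genotype-count table
and matching its printed statistics:

* **Pearson chi-square without continuity correction** for the 2x3
  genotype test (df = 2) and all 2x2 model tests. On the index SNP's
  printed counts this reproduces the genotype p = 0.031 and recessive
  p = 0.008 exactly at printed precision.
* **Wald confidence intervals** on the log odds ratio with z = 1.96:
  $\exp(\ln \widehat{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. This reproduces
  every targeted printed CI to two decimals.
* **Zero-cell policy: no Haldane-Anscombe 0.5 correction.** A zero
  case-exposed cell reports OR = 0 with CI (0, Inf), a zero denominator
  cell OR = Inf — matching the published "0.00 (0.00 - inf)" convention.
* **Genetic models** from a 2x3 table: allele (chromosomes, homozygotes
  doubled), dominant (carrier vs non-carrier), recessive (risk homozygote
  vs the rest). The *risk* allele need not be the minor allele — at the
  index SNP the risk allele has frequency 0.57 in controls — so the
  dichotomies take an explicit `risk_allele` argument and only fall back
  to minor-allele orientation when it is not given.
* **HWE in controls only** by default (standard practice; the source does
  not say), with the whole-sample option available.
* **Missing genotypes** are simply excluded; association runs on typed
  subjects.
* **No multiple-testing correction** by default, mirroring the analysis
  the package reproduces; callers can apply `p.adjust` downstream.

`adjusted_logistic()` is a thin, explicit coding layer over
`stats::glm(binomial)` (convergence tolerance 1e-10, at most 100
iterations); with no covariates and a dichotomous coding it equals the
cross-product odds ratio, which is tested to 1e-6. Perfect separation is
flagged (`separation = TRUE`, infinite estimate) rather than crashing.

`power_genetic()` computes the power of the model's 2x2 chi-square by the
standard noncentral chi-square approximation, with a simulation method
(binomial draws, actual test applied) as cross-check; the two agree to
within a few percent at study scale, and both exceed 0.5 for a recessive
odds ratio of 1.5 at ~850 subjects per arm.

Some printed odds ratios in published tables of this design are not
consistent with their own printed counts (e.g. an allele-model "1.31"
whose cross-product is 1.18). The package always recomputes from counts;
rows whose printed value cannot be reproduced from their counts are
excluded from the reproduction tests and noted here rather than matched.

## ChIP-qPCR quantification

`percent_input()` uses the standard dilution-adjusted delta-Ct form:
adjusted input Ct $= Ct_{input} - \log_2(1/f)$ for input fraction $f$
(default 1%), then $\%input = 100 \cdot 2^{(adjusted - Ct_{IP})}$. The
published summary values (1.71-3.20 with SEMs at or below 0.2) are treated
as percent-input group summaries — the only reading consistent with the
accompanying figure — and the generator plants them as truth.
`anova_oneway()` is the classical fixed-effects one-way ANOVA
(`oneway.test(var.equal = TRUE)`).

A published "1.49-fold enrichment" between the TT and GG groups matches
the *difference* of the printed means (3.20 - 1.71 = 1.49) but not their
*ratio* (1.87). `enrichment_ratio()` therefore reports both and asserts
neither as the definition. The single published plate's ANOVA p (0.027)
cannot be reproduced without the raw Ct values; the package checks instead
that plates generated at those group parameters reject homogeneity in the
large majority of replicates, and that the p-value is uniform under equal
means.

## The simulator: what it emulates, and what it does not

`simulation_config()` fixes the study conditions once:

* **Cohort**: 847 cases / 846 controls; control genotype frequencies
  (0.181, 0.495, 0.324) at the index SNP; planted recessive odds ratio
  1.31. Cases are drawn by the standard retrospective-sampling
  construction — multiply the odds of the risk homozygote by the planted
  OR and renormalize; no generative disease model is claimed. Covariates
  (sex, age, BMI, hypertension, diabetes, eGFR) are drawn per group from
  the published demographic means, with eGFR truncated to the group
  definitions (controls >= 60, cases <= 15 mL/min/1.73 m^2). Genotypes go
  missing at rate 1 - 0.993, mirroring per-SNP Ns slightly below cohort
  size.
* **Variants**: indel fraction 0.194 (the structural fraction of a
  ~59M-variant whole-genome call set of which ~11.4M were structural);
  call rates Beta(30, 2) truncated to [0.5, 1], putting roughly a quarter
  of sites below the 0.90 cutoff as in the screen being emulated (only the
  cutoff itself is stated there; the law is this package's choice); MAFs
  uniform on [0, 0.5]. Motif variants are placed at consensus-critical
  offsets (site destroyed) or fully degenerate offsets (site preserved)
  and verified at generation time; decoys are rejection-sampled to neither
  touch nor create any occurrence, so planted labels are exact.
* **qPCR**: per-sample percent-input drawn Normal(mean, SEM * sqrt(n)) and
  inverted to Ct pairs, so quantification tests have analytically known
  truth and the round trip is exact to floating point.

Determinism is a contract: the same configuration writes byte-identical
FASTA/VCF/BED/TSV/JSON files; stage sub-seeds are fixed offsets of the
configuration seed.

What the simulator deliberately does **not** model: linkage
disequilibrium, chromosome-scale genomes, read-level sequencing error,
population structure, genotyping batch effects. Passing tests therefore
demonstrate the correctness of the *computations* under the stated
statistical model, not robustness to the full messiness of real cohort
data.

## Problem sizes and numerical choices

The test suite and the reproduction script run at fixture scale chosen for
statistical sharpness: 30 kb genomes with 15 planted motifs and 60
variants for the funnel (exact ground-truth recovery), 500 simulated
cohorts at 841/846 subjects for parameter recovery (mean recovered log-OR
within 3 Monte-Carlo SE of log 1.31; 95% CI coverage within 0.03 of
nominal), 2000 replicates for power, 1 Mb for chance-match density, 200
plates for qPCR recovery. Degenerate inputs (empty variant sets, all-indel
input, monomorphic SNPs, zero cells, singleton qPCR groups, perfect
separation) are exercised explicitly and either handled or rejected with
informative errors.

## Known limitations

* The genome-scale funnel counts of the original screen (tens of millions
  of variants) depend on an inaccessible call set; only funnel *shape* and
  fixture-scale counts are verifiable here.
* The published per-genotype odds ratios attached to a 9-sample qPCR
  experiment have no stated model and are not reproduced.
* `adjusted_logistic()` reports Wald inference; profile-likelihood or
  Firth corrections for sparse tables are out of scope.
* The BED reader accepts BED3+name only — scores/strand beyond column 4
  are ignored on input (occurrence output is BED6).
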