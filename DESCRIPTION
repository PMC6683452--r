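Package: regsnpscreen
Title: Screening and Association Analysis of Variants in NF-kB Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A variant-aware screening funnel for regulatory single nucleotide
    polymorphisms in transcription factor binding sites, built around the
    degenerate NF-kB (p50-p65) consensus GGGRNNYYCC. Filters a variant call
    set by structural class and call rate, scans a reference genome for
    degenerate motif occurrences on both strands, classifies each allele's
    effect on the binding site (preserved, destroyed, created), confirms
    candidates against ChIP-seq peak intervals, and carries the surviving
    SNPs into case-control association analysis (Hardy-Weinberg equilibrium,
    genotype chi-square, allele/dominant/recessive odds ratios with Wald
    confidence intervals, covariate-adjusted logistic regression, and power
    computation) and ChIP-qPCR percent-input quantification with one-way
    ANOVA. Includes a seeded synthetic-data generator that emulates every
    input the pipeline consumes, with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
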