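# Association statistics, checked against hand arithmetic, published table
# values recomputed from their genotype counts, and Monte-Carlo oracles.

test_that("HWE chi-square matches hand computation on published controls", {
  counts <- c(153, 419, 274)
  h <- hwe_test(counts)
  # independent hand computation
  n <- sum(counts); p <- (2 * 153 + 419) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2_hand <- sum((counts - e)^2 / e)
  expect_equal(h$chi2, chi2_hand, tolerance = 1e-12)
  expect_gt(h$p, 0.05)          # consistent with equilibrium
  expect_equal(h$df, 1L)
})

test_that("HWE degenerate cases: perfect equilibrium and total disequilibrium", {
  h <- hwe_test(c(25, 50, 25))
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  h2 <- hwe_test(c(100, 0, 100))
  expect_equal(h2$chi2, 200)    # chi2 = n when heterozygotes are absent at p = 1/2
  expect_lt(h2$p, 1e-6)
  expect_error(hwe_test(c(0, 0, 0)), "zero total")
})

test_that("genotype chi-square reproduces the published p = 0.031", {
  gc <- esrd_genotype_counts()[["rs9395890"]]
  p <- genotype_chisq(gc)$p.value
  expect_equal(round(p, 3), 0.031)
})

test_that("identical genotype rows give p = 1; empty columns reduce df", {
  gc <- genotype_counts("x", c(10, 20, 30), c(10, 20, 30))
  expect_equal(genotype_chisq(gc)$p.value, 1)
  gc0 <- genotype_counts("y", c(10, 20, 0), c(12, 18, 0))
  expect_warning(ht <- genotype_chisq(gc0), "all-zero")
  expect_equal(unname(ht$parameter), 1)
})

test_that("genotype chi-square p agrees with a fixed-margin Monte-Carlo oracle", {
  m <- matrix(c(20, 30, 10, 10, 25, 25), nrow = 2, byrow = TRUE)
  gc <- genotype_counts("mc", m[1, ], m[2, ])
  p_asym <- genotype_chisq(gc)$p.value
  chi2_obs <- unname(genotype_chisq(gc)$statistic)
  set.seed(404)
  B <- 20000
  sims <- r2dtable(B, rowSums(m), colSums(m))
  chi2_of <- function(t) {
    e <- outer(rowSums(t), colSums(t)) / sum(t)
    sum((t - e)^2 / e)
  }
  p_mc <- mean(vapply(sims, chi2_of, numeric(1)) >= chi2_obs - 1e-9)
  expect_lt(abs(p_asym - p_mc), 4 * sqrt(p_mc * (1 - p_mc) / B) + 0.01)
})

test_that("model tables collapse published genotype counts correctly", {
  gc <- esrd_genotype_counts()[["rs9395890"]]
  tabs <- build_model_tables(gc)
  # allele counts: chromosomes
  expect_equal(tabs$allele["control", ], c(exposed = 967, unexposed = 725))
  expect_equal(tabs$allele["case", ], c(exposed = 1027, unexposed = 655))
  # recessive: TT vs carrier
  expect_equal(tabs$recessive["control", ], c(exposed = 274, unexposed = 572))
  expect_equal(tabs$recessive["case", ], c(exposed = 324, unexposed = 517))
  # dominant: carrier vs GG
  expect_equal(tabs$dominant["control", ], c(exposed = 693, unexposed = 153))
  expect_equal(tabs$dominant["case", ], c(exposed = 703, unexposed = 138))
  # degenerate input
  z <- build_model_tables(genotype_counts("z", c(0, 0, 0), c(0, 0, 0)))
  expect_true(all(vapply(z, sum, numeric(1)) == 0))
})

test_that("odds ratios and Wald CIs reproduce published rows to 2 dp", {
  gc <- esrd_genotype_counts()
  tabs <- build_model_tables(gc[["rs9395890"]])

  rec <- odds_ratio(tabs$recessive)
  expect_equal(round(rec$or, 2), 1.31)
  expect_equal(round(rec$ci, 2), c(1.07, 1.60))
  expect_equal(round(rec$p, 3), 0.008)

  dom <- odds_ratio(tabs$dominant)
  expect_equal(round(dom$or, 2), 1.12)
  expect_equal(round(dom$ci, 2), c(0.87, 1.45))

  # per-genotype ORs vs the reference homozygote
  gvr <- function(snp) {
    m <- gc[[snp]]$counts
    odds_ratio(matrix(c(m["case", 3], m["case", 1], m["control", 3],
                        m["control", 1]), nrow = 2, byrow = TRUE))
  }
  r <- gvr("rs11826681")
  expect_equal(round(r$or, 2), 1.22); expect_equal(round(r$ci, 2), c(0.91, 1.63))
  r <- gvr("rs7284245")
  expect_equal(round(r$or, 2), 0.82); expect_equal(round(r$ci, 2), c(0.44, 1.54))
  r <- gvr("rs59118205")
  expect_equal(round(r$or, 2), 0.49); expect_equal(round(r$ci, 2), c(0.09, 2.71))
  r <- gvr("rs78229468")
  expect_equal(round(r$or, 2), 2.00); expect_equal(round(r$ci, 2), c(0.60, 6.68))
})

test_that("zero-cell policy: no continuity correction, 0 and Inf endpoints", {
  # zero case-exposed cell (observed at one published SNP): OR 0, CI (0, Inf)
  r0 <- odds_ratio(c(0, 665, 1, 638))
  expect_equal(r0$or, 0)
  expect_equal(r0$ci, c(0, Inf))
  rInf <- odds_ratio(c(5, 0, 3, 10))
  expect_equal(rInf$or, Inf)
  r_balanced <- odds_ratio(c(10, 10, 10, 10))
  expect_equal(r_balanced$or, 1)
  expect_equal(log(r_balanced$ci[1]), -log(r_balanced$ci[2]))  # symmetric on log scale
  expect_error(odds_ratio(c(-1, 2, 3, 4)), "non-negative")
})

test_that("odds-ratio invariances hold on random tables", {
  set.seed(55)
  for (rep in 1:25) {
    cells <- rpois(4, 40) + 1
    r <- odds_ratio(cells)
    # antisymmetry: swapping exposure columns inverts OR, mirrors CI
    r_swap <- odds_ratio(cells[c(2, 1, 4, 3)])
    expect_equal(r_swap$or, 1 / r$or, tolerance = 1e-12)
    expect_equal(r_swap$ci, rev(1 / r$ci), tolerance = 1e-12)
    # scaling one group's row leaves the OR unchanged
    r_scaled <- odds_ratio(c(cells[1:2] * 3, cells[3:4]))
    expect_equal(r_scaled$or, r$or, tolerance = 1e-12)
    # CI contains the point estimate
    expect_true(r$ci[1] <= r$or && r$or <= r$ci[2])
  }
})

test_that("crude logistic fit equals the cross-product odds ratio", {
  gc <- esrd_genotype_counts()[["rs9395890"]]
  subj <- subjects_from_counts(gc)
  fit <- adjusted_logistic(subj, coding = "recessive",
                           covariates = character(0), risk_allele = "T")
  crude <- odds_ratio(build_model_tables(gc)$recessive)
  expect_false(fit$adjusted)
  expect_equal(fit$or, crude$or, tolerance = 1e-6)
  expect_equal(fit$ci, crude$ci, tolerance = 1e-3)  # Wald z vs same formula
})

test_that("adjustment removes confounding bias that the crude OR carries", {
  set.seed(66)
  true_or <- 1.6
  nrep <- 150; n <- 600
  lors <- replicate(nrep, {
    z <- rbinom(n, 1, 0.5)                      # confounder
    x <- rbinom(n, 1, ifelse(z == 1, 0.55, 0.15))  # exposure depends on z
    p <- plogis(-1.2 + log(true_or) * x + 1.3 * z)
    y <- rbinom(n, 1, p)
    subj <- data.frame(group = ifelse(y == 1, "case", "control"),
                       genotype = ifelse(x == 1, "TT", "GT"), z = z)
    adj <- adjusted_logistic(subj, coding = "recessive", covariates = "z",
                             risk_allele = "T")
    crude <- adjusted_logistic(subj, coding = "recessive",
                               covariates = character(0), risk_allele = "T")
    c(adj = log(adj$or), crude = log(crude$or))
  })
  mean_adj <- mean(lors["adj", ]); se_adj <- sd(lors["adj", ]) / sqrt(nrep)
  mean_crude <- mean(lors["crude", ])
  expect_lt(abs(mean_adj - log(true_or)), 4 * se_adj)
  expect_gt(mean_crude, log(true_or) + 0.1)   # crude is biased upward here
})

test_that("perfect separation is flagged rather than crashing", {
  subj <- data.frame(group = rep(c("case", "control"), each = 20),
                     genotype = rep(c("TT", "GG"), each = 20))
  fit <- adjusted_logistic(subj, coding = "recessive",
                           covariates = character(0), risk_allele = "T")
  expect_true(fit$separation)
  expect_true(is.infinite(fit$or))
})

test_that("single-group input is rejected", {
  subj <- data.frame(group = "case", genotype = "TT")[rep(1, 10), ]
  expect_error(adjusted_logistic(subj, covariates = character(0)),
               "empty control group")
  subj2 <- data.frame(group = "control", genotype = "TT")[rep(1, 10), ]
  expect_error(genotype_counts_from_subjects(subj2), "empty case group")
})

test_that("risk-allele orientation controls the recessive dichotomy", {
  subj <- rbind(
    data.frame(group = "control",
               genotype = rep(c("GG", "GT", "TT"), c(18, 50, 32))),
    data.frame(group = "case",
               genotype = rep(c("GG", "GT", "TT"), c(15, 45, 40))))
  gc_t <- genotype_counts_from_subjects(subj, risk_allele = "T")
  expect_equal(colnames(gc_t$counts), c("GG", "GT", "TT"))
  expect_equal(unname(gc_t$counts["control", ]), c(18, 50, 32))
  gc_g <- genotype_counts_from_subjects(subj, risk_allele = "G")
  expect_equal(colnames(gc_g$counts), c("TT", "GT", "GG"))
})

test_that("power equals alpha at OR 1 and grows with n and effect size", {
  f <- c(0.181, 0.495, 0.324)
  expect_equal(as.numeric(power_genetic(800, 800, 1.0, f)), 0.05,
               tolerance = 1e-12)
  pw <- vapply(c(200, 500, 1000), function(n) power_genetic(n, n, 1.4, f),
               numeric(1))
  expect_true(all(diff(pw) > 0))
  pw_or <- vapply(c(1.2, 1.5, 2.0), function(or) power_genetic(500, 500, or, f),
                  numeric(1))
  expect_true(all(diff(pw_or) > 0))
})

test_that("approximate power agrees with simulated power at study scale", {
  f <- c(0.181, 0.495, 0.324)
  p_approx <- power_genetic(841, 846, 1.5, f)
  p_sim <- power_genetic(841, 846, 1.5, f, method = "simulation",
                         nsim = 2000, seed = 99)
  expect_gt(p_approx, 0.5)
  expect_gt(p_sim, 0.5)
  expect_lt(abs(p_approx - p_sim), 0.05)
})

test_that("degenerate power inputs are rejected", {
  expect_error(power_genetic(100, 100, 1.5, c(1, 0, 0)), "degenerate")
  expect_error(power_genetic(100, 100, 0, c(0.25, 0.5, 0.25)))
})
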