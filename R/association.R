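## Case-control statistical battery: Hardy-Weinberg equilibrium, genotype
## chi-square, allele/dominant/recessive 2x2 odds ratios with Wald CIs,
## covariate-adjusted logistic regression, and genetic power.
##
## Conventions, chosen to reproduce printed epidemiological tables from
## their genotype counts: Pearson chi-square WITHOUT continuity correction
## throughout; Wald log-scale CI with z = 1.96; no Haldane-Anscombe 0.5
## correction for zero cells (a zero case-exposed cell reports OR = 0 with
## CI (0, Inf)).

#' Case-control genotype counts
#'
#' Container for a 2x3 genotype count table. Genotype columns are ordered
#' (major homozygote, heterozygote, minor homozygote); rows are control and
#' case. Row sums may be below the cohort sizes (missing genotypes).
#'
#' @param snp SNP identifier.
#' @param control,case Length-3 non-negative integer vectors of genotype
#'   counts `(AA, Aa, aa)` with `a` the minor/risk allele.
#' @param genotypes Optional genotype labels, e.g. `c("GG","GT","TT")`.
#' @return An object of class `"genotype_counts"` wrapping the 2x3 matrix.
#' @examples
#' gc <- genotype_counts("rs9395890", control = c(153, 419, 274),
#'                       case = c(138, 379, 324),
#'                       genotypes = c("GG", "GT", "TT"))
#' @export
genotype_counts <- function(snp, control, case, genotypes = c("AA", "Aa", "aa")) {
  stopifnot(length(control) == 3L, length(case) == 3L, length(genotypes) == 3L)
  if (any(c(control, case) < 0) || anyNA(c(control, case))) {
    stop("genotype counts must be non-negative and non-missing")
  }
  m <- rbind(control = as.numeric(control), case = as.numeric(case))
  colnames(m) <- genotypes
  structure(list(snp = snp, counts = m), class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype counts for", x$snp, "\n")
  print(x$counts)
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square with 1 degree of freedom comparing observed genotype
#' counts to the counts expected under Hardy-Weinberg proportions at the
#' sample allele frequency. Conventionally applied to controls only.
#'
#' @param counts Length-3 vector of genotype counts `(AA, Aa, aa)`.
#' @return List with `chi2`, `df` (1) and `p`.
#' @examples
#' hwe_test(c(153, 419, 274))$p   # > 0.05: consistent with HWE
#' hwe_test(c(25, 50, 25))$chi2   # exactly 0
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3L)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("zero total genotype count")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expected == 0)) {
    ## monomorphic: observed equals expected by construction
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  list(chi2 = unname(chi2), df = 1L,
       p = stats::pchisq(unname(chi2), df = 1L, lower.tail = FALSE))
}

#' Genotype-distribution chi-square test
#'
#' Pearson chi-square (no continuity correction) on the 2x3
#' group-by-genotype table, df = 2. Genotype columns that are empty in both
#' groups are dropped with a warning (df reduced accordingly).
#'
#' @param counts A [`genotype_counts`][genotype_counts] object or a 2x3
#'   matrix (rows control/case).
#' @return An `htest` object from [stats::chisq.test()].
#' @export
genotype_chisq <- function(counts) {
  m <- if (inherits(counts, "genotype_counts")) counts$counts else as.matrix(counts)
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d all-zero genotype column(s); df reduced", sum(empty)))
    m <- m[, !empty, drop = FALSE]
  }
  suppressWarnings(stats::chisq.test(m, correct = FALSE))
}

#' Collapse genotype counts into allele / dominant / recessive 2x2 tables
#'
#' The allele table counts chromosomes (homozygotes contribute two); the
#' dominant model compares minor-allele carriers (`Aa + aa`) to `AA`; the
#' recessive model compares minor homozygotes `aa` to everyone else.
#'
#' @param counts A [`genotype_counts`][genotype_counts] object.
#' @return Named list of 2x2 matrices (`allele`, `dominant`, `recessive`),
#'   each laid out rows = (case, control), columns = (exposed, unexposed).
#' @export
build_model_tables <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  m <- counts$counts
  t2 <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
    matrix(c(case_exp, case_unexp, ctrl_exp, ctrl_unexp),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("case", "control"), c("exposed", "unexposed")))
  }
  list(
    allele = t2(2 * m["case", 3] + m["case", 2], 2 * m["case", 1] + m["case", 2],
                2 * m["control", 3] + m["control", 2],
                2 * m["control", 1] + m["control", 2]),
    dominant = t2(m["case", 2] + m["case", 3], m["case", 1],
                  m["control", 2] + m["control", 3], m["control", 1]),
    recessive = t2(m["case", 3], m["case", 1] + m["case", 2],
                   m["control", 3], m["control", 1] + m["control", 2])
  )
}

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' `OR = ad / bc` on the layout (a = case-exposed, b = case-unexposed,
#' c = control-exposed, d = control-unexposed); the 95% CI is
#' `exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` and the p-value is
#' the Pearson chi-square on the 2x2 without continuity correction.
#' Zero-cell policy (no 0.5 correction): a zero case-exposed (or
#' control-unexposed) cell reports OR = 0 with CI (0, Inf); a zero
#' denominator cell reports OR = Inf with CI (0, Inf).
#'
#' @param t A 2x2 matrix laid out rows = (case, control), columns =
#'   (exposed, unexposed), as produced by [build_model_tables()], or a
#'   length-4 vector `(a, b, c, d)`.
#' @return An object of class `"association_result"`: list with `or`,
#'   `ci` (length-2), `p`, `chi2`, `table`, `adjusted = FALSE`.
#' @examples
#' tab <- matrix(c(324, 517, 274, 572), nrow = 2, byrow = TRUE)
#' odds_ratio(tab)   # OR 1.31 (1.07-1.60), p 0.008
#' @export
odds_ratio <- function(t) {
  if (is.matrix(t)) {
    stopifnot(all(dim(t) == c(2L, 2L)))
    cells <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  } else {
    stopifnot(length(t) == 4L)
    cells <- as.numeric(t)
    t <- matrix(cells, nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("exposed", "unexposed")))
  }
  if (anyNA(cells) || any(cells < 0)) stop("2x2 cells must be non-negative")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  num <- a * d; den <- b * c
  if (den > 0 && num > 0) {
    or <- num / den
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  } else if (num == 0 && den == 0) {
    or <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else if (num == 0) {
    or <- 0; ci <- c(0, Inf)
  } else {
    or <- Inf; ci <- c(0, Inf)
  }
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    ht <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
    chi2 <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(or = or, ci = ci, p = p, chi2 = chi2, table = t,
                 adjusted = FALSE, covariates = character(0)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%sOR %.2f (95%% CI %.2f-%.2f), p = %.3f%s\n",
              if (isTRUE(x$adjusted)) "adjusted " else "",
              x$or, x$ci[1], x$ci[2], x$p,
              if (isTRUE(x$separation)) "  [separation flagged]" else ""))
  invisible(x)
}

## Count copies of the minor allele in genotype strings like "GT".
.minor_allele_dose <- function(genotype, minor) {
  vapply(strsplit(genotype, "", fixed = TRUE), function(g) sum(g == minor),
         numeric(1))
}

#' Covariate-adjusted logistic regression for a genetic term
#'
#' Maximum-likelihood logistic regression of case status on a coded genetic
#' term plus covariates, via [stats::glm()]. The genetic term is coded from
#' two-letter genotype strings: `"recessive"` (minor homozygote vs rest),
#' `"dominant"` (carrier vs major homozygote), `"additive"` (minor-allele
#' dose 0/1/2) or `"genotype"` (two dummy terms). With an empty covariate
#' set and a dichotomous coding, the estimate equals the cross-product odds
#' ratio of the corresponding 2x2 table.
#'
#' @param subjects Data frame with a `group` column (`"control"`/`"case"`),
#'   a genotype column, and the covariate columns.
#' @param snp_col Name of the genotype column (default `"genotype"`).
#' @param coding Genetic coding (see above).
#' @param covariates Covariate column names to adjust for (default
#'   `c("sex","age","bmi","htn","dm")`; use `character(0)` for a crude fit).
#' @param risk_allele Allele whose dose is coded (the exposure allele of the
#'   dominant/recessive dichotomy). Defaults to the minor allele in
#'   controls, but the risk allele of a published model need not be minor --
#'   pass it explicitly when it is not.
#' @return An `"association_result"` for the genetic term (`or`, Wald `ci`,
#'   Wald `p`, `adjusted = TRUE` if covariates were used, `separation` flag,
#'   and the full `fit`). For `coding = "genotype"` the fields are matrices
#'   with one row per non-reference genotype.
#' @export
adjusted_logistic <- function(subjects, snp_col = "genotype",
                              coding = c("recessive", "dominant", "additive", "genotype"),
                              covariates = c("sex", "age", "bmi", "htn", "dm"),
                              risk_allele = NULL) {
  coding <- match.arg(coding)
  stopifnot(is.data.frame(subjects), "group" %in% names(subjects),
            snp_col %in% names(subjects))
  df <- subjects[!is.na(subjects[[snp_col]]), , drop = FALSE]
  if (length(covariates) > 0L) {
    missing_cov <- setdiff(covariates, names(df))
    if (length(missing_cov) > 0L) {
      stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
    }
    df <- df[stats::complete.cases(df[covariates]), , drop = FALSE]
  }
  y <- as.integer(df$group == "case")
  if (all(y == 1L)) stop("empty control group")
  if (all(y == 0L)) stop("empty case group")
  geno <- toupper(df[[snp_col]])
  alleles <- sort(unique(unlist(strsplit(geno, "", fixed = TRUE))))
  if (is.null(risk_allele)) {
    ctrl_dose <- unlist(strsplit(geno[y == 0L], "", fixed = TRUE))
    freqs <- table(factor(ctrl_dose, levels = alleles))
    risk_allele <- names(freqs)[which.min(freqs)]
  }
  dose <- .minor_allele_dose(geno, risk_allele)
  g <- switch(coding,
              recessive = as.numeric(dose == 2),
              dominant = as.numeric(dose >= 1),
              additive = dose,
              genotype = factor(dose, levels = c(0, 1, 2)))
  dat <- data.frame(y = y, g = g, df[covariates], check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  sep <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  sm <- summary(fit)$coefficients
  rows <- grep("^g", rownames(sm), value = TRUE)
  est <- sm[rows, "Estimate"]
  se <- sm[rows, "Std. Error"]
  or <- exp(est)
  if (sep) or[abs(est) > 15] <- ifelse(est[abs(est) > 15] > 0, Inf, 0)
  ci <- cbind(exp(est - 1.96 * se), exp(est + 1.96 * se))
  p <- sm[rows, "Pr(>|z|)"]
  one <- length(rows) == 1L
  structure(list(or = if (one) unname(or) else or,
                 ci = if (one) as.numeric(ci[1, ]) else ci,
                 p = if (one) unname(p) else p,
                 chi2 = NA_real_,
                 coding = coding,
                 adjusted = length(covariates) > 0L,
                 covariates = covariates,
                 separation = sep,
                 risk_allele = risk_allele,
                 fit = fit),
            class = "association_result")
}

## Exposure probability under a genetic model given genotype frequencies
## (major hom, het, minor hom).
.model_exposure <- function(freqs, model) {
  switch(model,
         recessive = freqs[3],
         dominant = freqs[2] + freqs[3],
         allele = freqs[3] + freqs[2] / 2)
}

#' Power of the case-control chi-square test under a genetic model
#'
#' Computes the power of the Pearson chi-square test (alpha level, 1 df) on
#' the model's 2x2 dichotomy, when cases arise from applying a target odds
#' ratio to the control exposure odds. The default is a noncentral
#' chi-square approximation; `method = "simulation"` draws binomial
#' replicates and applies the actual test.
#'
#' @param n_case,n_control Group sizes.
#' @param target_or Odds ratio to detect (> 0).
#' @param control_genotype_freqs Length-3 control genotype frequency vector
#'   (major hom, het, minor hom), summing to 1.
#' @param model `"recessive"`, `"dominant"` or `"allele"` (allele counts use
#'   2n chromosomes).
#' @param alpha Test level (default 0.05).
#' @param method `"approx"` (noncentral chi-square) or `"simulation"`.
#' @param nsim Replicates for the simulation method (default 2000).
#' @param seed Optional seed for the simulation method.
#' @return Power estimate in [0, 1], with the method as an attribute.
#' @examples
#' power_genetic(841, 846, 1.5, c(0.181, 0.495, 0.324))  # > 0.5
#' @export
power_genetic <- function(n_case, n_control, target_or, control_genotype_freqs,
                          model = c("recessive", "dominant", "allele"),
                          alpha = 0.05, method = c("approx", "simulation"),
                          nsim = 2000L, seed = NULL) {
  model <- match.arg(model)
  method <- match.arg(method)
  stopifnot(n_case > 0, n_control > 0, target_or > 0, alpha > 0, alpha < 1)
  f <- control_genotype_freqs
  if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-6) {
    stop("control_genotype_freqs must be a 3-vector summing to 1")
  }
  p0 <- .model_exposure(f, model)
  if (p0 <= 0 || p0 >= 1) stop("degenerate exposure frequency under this model")
  odds1 <- target_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  n1 <- if (model == "allele") 2 * n_case else n_case
  n2 <- if (model == "allele") 2 * n_control else n_control
  if (method == "approx") {
    pbar <- (n1 * p1 + n2 * p0) / (n1 + n2)
    ncp <- (p1 - p0)^2 / (pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    crit <- stats::qchisq(1 - alpha, df = 1)
    power <- stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    x1 <- stats::rbinom(nsim, n1, p1)
    x2 <- stats::rbinom(nsim, n2, p0)
    ## vectorized Pearson chi-square on the 2x2 (no continuity correction)
    a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
    n <- n1 + n2
    chi2 <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    chi2[!is.finite(chi2)] <- 0
    power <- mean(chi2 > stats::qchisq(1 - alpha, df = 1))
  }
  structure(unname(power), method = method)
}

#' Tabulate case-control genotype counts from a subject table
#'
#' @param subjects Subject data frame (see [read_subjects()]).
#' @param snp_col Genotype column name.
#' @param snp SNP identifier for the result (defaults to `snp_col`).
#' @param risk_allele Allele placed in the third (exposure homozygote)
#'   column; defaults to the minor allele in controls.
#' @return A [`genotype_counts`][genotype_counts] object with genotype
#'   columns ordered (non-risk hom, het, risk hom); missing genotypes are
#'   excluded.
#' @export
genotype_counts_from_subjects <- function(subjects, snp_col = "genotype",
                                          snp = snp_col, risk_allele = NULL) {
  stopifnot("group" %in% names(subjects), snp_col %in% names(subjects))
  df <- subjects[!is.na(subjects[[snp_col]]), , drop = FALSE]
  if (!any(df$group == "case")) stop("empty case group")
  if (!any(df$group == "control")) stop("empty control group")
  geno <- toupper(df[[snp_col]])
  alleles <- sort(unique(unlist(strsplit(geno, "", fixed = TRUE))))
  if (length(alleles) > 2L) stop("more than two alleles in genotype column")
  if (is.null(risk_allele)) {
    ctrl_alleles <- unlist(strsplit(geno[df$group == "control"], "", fixed = TRUE))
    tab <- table(factor(ctrl_alleles, levels = alleles))
    risk_allele <- names(tab)[which.min(tab)]
  }
  minor <- toupper(risk_allele)
  major <- setdiff(alleles, minor)
  if (length(major) == 0L) major <- minor  # monomorphic
  levels3 <- c(paste0(major, major),
               paste(sort(c(major, minor)), collapse = ""),
               paste0(minor, minor))
  norm <- vapply(strsplit(geno, "", fixed = TRUE),
                 function(g) paste(sort(g), collapse = ""), character(1))
  levels3_sorted <- vapply(strsplit(levels3, "", fixed = TRUE),
                           function(g) paste(sort(g), collapse = ""), character(1))
  gf <- factor(norm, levels = unique(levels3_sorted))
  ctl <- as.integer(table(gf[df$group == "control"]))
  cas <- as.integer(table(gf[df$group == "case"]))
  if (length(ctl) < 3L) { ctl <- c(ctl, rep(0L, 3 - length(ctl)))
                          cas <- c(cas, rep(0L, 3 - length(cas))) }
  genotype_counts(snp, control = ctl, case = cas, genotypes = levels3)
}
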