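## ChIP-qPCR percent-input quantification, per-genotype summaries, one-way
## ANOVA, and the enrichment comparison between genotype groups.

#' Percent-input from paired IP / input Ct values
#'
#' Standard dilution-adjusted delta-Ct quantification: the input Ct is first
#' adjusted for the fraction of chromatin reserved as input
#' (`ct_input - log2(1 / input_fraction)`), then
#' `percent = 100 * 2^(adjusted_input_ct - ct_ip)`. Equal IP and adjusted
#' input Ct gives 100%; each extra IP cycle halves the value.
#'
#' @param ct_ip,ct_input Ct values (finite, positive); vectorized.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1]
#'   (default 0.01, i.e. a 1% input).
#' @return Percent-input values (percent scale).
#' @examples
#' percent_input(25, 25 + log2(1 / 0.01))          # 100
#' percent_input(26, 25 + log2(1 / 0.01))          # 50
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]")
  }
  if (any(!is.finite(ct_ip)) || any(!is.finite(ct_input)) ||
      any(ct_ip <= 0) || any(ct_input <= 0)) {
    stop("Ct values must be finite and positive")
  }
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' Per-group mean, SEM and n
#'
#' @param values Numeric measurements (e.g. percent-input).
#' @param groups Grouping vector (e.g. genotypes), same length.
#' @return Data frame with columns `group`, `n`, `mean`, `sem`
#'   (`sd / sqrt(n)`; `NA` with a warning for singleton groups).
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  if (any(is.na(values)) || any(is.na(groups))) stop("missing values or groups")
  gl <- unique(groups)
  out <- do.call(rbind, lapply(gl, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n == 1L)) {
    warning("group(s) with n = 1: SEM undefined for ",
            paste(out$group[out$n == 1L], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Classical one-way fixed-effects ANOVA
#'
#' @param values Numeric measurements.
#' @param groups Grouping vector; at least 2 groups, each with n >= 2.
#' @return List with `F`, `df` (between, within) and `p`.
#' @export
anova_oneway <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(as.character(groups))
  tab <- table(groups)
  if (nlevels(groups) < 2L) stop("ANOVA requires at least 2 groups")
  if (any(tab < 2L)) {
    stop("ANOVA requires n >= 2 per group (violated by: ",
         paste(names(tab)[tab < 2L], collapse = ", "), ")")
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ht$statistic),
       df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fold enrichment between two group means
#'
#' Reports both the ratio `mean_a / mean_b` and the difference
#' `mean_a - mean_b`. Both are returned because a published "fold
#' enrichment" between percent-input means can match either convention;
#' neither is asserted as the definition.
#'
#' @param mean_a,mean_b Group means; `mean_b > 0`.
#' @return List with `ratio` and `difference`.
#' @examples
#' enrichment_ratio(3.20, 1.71)  # ratio 1.87, difference 1.49
#' @export
enrichment_ratio <- function(mean_a, mean_b) {
  if (mean_b == 0) stop("zero denominator mean")
  list(ratio = mean_a / mean_b, difference = mean_a - mean_b)
}
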