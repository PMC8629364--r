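# Enrichment statistics: trans-splicing status versus conservation class
# and cell-type specificity, with fold enrichments and chi-square tests.

#' Cross-tabulate trans-splicing status by conservation class
#'
#' Exact counts of genes by (TS, nonTS) x (conserved, non-conserved,
#' non-coding), optionally restricted to a gene-id subset. Genes with an
#' unknown ts_status or cons_class are excluded from the table and
#' tallied in the `"excluded"` attribute.
#'
#' @param genes A `gene_models` data.frame.
#' @param subset Optional character vector of gene ids (e.g. the
#'   neoblast-enriched set).
#' @return A 2x3 contingency matrix with an `"excluded"` attribute.
#' @export
conservation_crosstab <- function(genes, subset = NULL) {
  if (!is.null(subset)) {
    genes <- genes[genes$gene_id %in% subset, , drop = FALSE]
  }
  known <- genes$ts_status %in% c("TS", "nonTS") &
    genes$cons_class %in% c("conserved", "non-conserved", "non-coding")
  tab <- table(
    factor(genes$ts_status[known], levels = c("TS", "nonTS")),
    factor(genes$cons_class[known],
           levels = c("conserved", "non-conserved", "non-coding"))
  )
  m <- matrix(as.integer(tab), nrow = 2, dimnames = dimnames(tab))
  attr(m, "excluded") <- sum(!known)
  m
}

#' Per-column percentage breakdown of a cross-tab
#'
#' Fractions within each ts_status row, reported to one decimal so they
#' line up with printed precision.
#'
#' @param crosstab Matrix from [conservation_crosstab()].
#' @param digits Decimal digits (default 1).
#' @return A matrix of row-wise percentages.
#' @export
crosstab_fractions <- function(crosstab, digits = 1) {
  t(apply(crosstab, 1, function(r) round(100 * r / sum(r), digits)))
}

#' Fold enrichment of a property in a subset versus the genome
#'
#' `fold = (subset_with / subset_total) / (genome_with / genome_total)`,
#' reported to two decimals.
#'
#' @param subset_with,subset_total Counts in the subset.
#' @param genome_with,genome_total Genome-wide counts.
#' @return A list `subset_fraction`, `genome_fraction`, `fold`
#'   (unrounded) and `fold_2dp`.
#' @export
#' @examples
#' fold_enrichment(728, 752, 15201, 33525)$fold_2dp  # 2.13
fold_enrichment <- function(subset_with, subset_total, genome_with,
                            genome_total) {
  stopifnot(subset_total > 0, genome_total > 0)
  if (genome_with == 0) stop("genome_with is 0: fold enrichment undefined")
  sf <- subset_with / subset_total
  gf <- genome_with / genome_total
  list(subset_fraction = sf, genome_fraction = gf,
       fold = sf / gf, fold_2dp = round(sf / gf, 2))
}

#' Chi-square goodness-of-fit test
#'
#' `chi2 = sum((O - E)^2 / E)` with `E = proportion * sum(O)`,
#' `df = cells - 1`, and the p-value from the chi-square upper tail.
#'
#' @param observed Non-negative count vector.
#' @param expected_proportions Proportions summing to 1.
#' @return A list `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_gof(c(60, 40), c(0.5, 0.5))$chi2  # 4
chi_square_gof <- function(observed, expected_proportions) {
  stopifnot(length(observed) == length(expected_proportions),
            all(observed >= 0))
  if (abs(sum(expected_proportions) - 1) > 1e-9) {
    stop("expected_proportions must sum to 1")
  }
  E <- expected_proportions * sum(observed)
  if (any(E == 0 & observed > 0)) {
    stop("expected count 0 with observed > 0")
  }
  keep <- E > 0
  chi2 <- sum((observed[keep] - E[keep])^2 / E[keep])
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' 2x2 contingency chi-square (no continuity correction)
#'
#' Convenience wrapper around [stats::chisq.test()] for subset-versus-
#' rest contingency tables.
#'
#' @param tab A 2x2 count matrix.
#' @return A list `chi2`, `df`, `p_value`.
#' @export
contingency_chi2 <- function(tab) {
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
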