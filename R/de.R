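#' Wilcoxon rank-sum differential expression between two groups
#'
#' Per miRNA: a two-sided Wilcoxon rank-sum test between the group
#' observations (cells or pooled pseudo-samples) and a fold change
#' `log2((mean_A + eps) / (mean_B + eps))` on expression-scale values. A
#' miRNA is called significant when `p < alpha` AND
#' `|log2FC| >= min_abs_log2fc`. Inputs must be on an expression scale
#' (nonnegative): fold changes of z-scored values are meaningless, so
#' negative-valued inputs are rejected — inverse-transform model predictions
#' first (`predict(..., output = "expression")`).
#'
#' @param x_a,x_b observations x miRNAs matrices for the two groups (same
#'   columns), at least 2 rows each.
#' @param min_abs_log2fc fold-change filter (default 0.25).
#' @param alpha significance level on the (possibly adjusted) p-value.
#' @param pseudocount `eps` guarding the ratio (default 1e-9).
#' @param p_adjust `"none"` (default; raw p-values, the single-cell
#'   convention) or `"BH"`.
#' @return data.frame of class `de_table`: `mirna`, `mean_a`, `mean_b`,
#'   `log2fc`, `p_value`, `p_adjusted`, `direction` (`up` = higher in group
#'   A), `significant`.
#' @export
wilcoxon_de <- function(x_a, x_b, min_abs_log2fc = 0.25, alpha = 0.05,
                        pseudocount = 1e-9, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  a <- as_matrix(x_a); b <- as_matrix(x_b)
  if (!identical(colnames(a), colnames(b)) || ncol(a) != ncol(b)) {
    stop("the two groups must share the same miRNA columns")
  }
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least 2 observations (",
         nrow(a), " vs ", nrow(b), ")")
  }
  if (min(a) < 0 || min(b) < 0) {
    stop("negative values: fold changes need expression-scale input; ",
         "inverse-transform z-scored predictions first")
  }
  m <- ncol(a)
  mean_a <- colMeans(a); mean_b <- colMeans(b)
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  p <- vapply(seq_len(m), function(k) {
    if (sd(a[, k]) == 0 && sd(b[, k]) == 0 && mean_a[k] == mean_b[k]) {
      return(1)
    }
    suppressWarnings(wilcox.test(a[, k], b[, k], exact = FALSE)$p.value)
  }, numeric(1L))
  p[is.na(p)] <- 1
  padj <- if (p_adjust == "BH") p.adjust(p, "BH") else p
  out <- data.frame(mirna = colnames(a) %||% sprintf("col%d", seq_len(m)),
                    mean_a = mean_a, mean_b = mean_b, log2fc = lfc,
                    p_value = p, p_adjusted = padj,
                    direction = ifelse(lfc > 0, "up",
                                       ifelse(lfc < 0, "down", "none")),
                    significant = padj < alpha & abs(lfc) >= min_abs_log2fc,
                    row.names = NULL)
  class(out) <- c("de_table", class(out))
  out
}

#' Sensitivity and accuracy against a reference dysregulated-miRNA list
#'
#' Sensitivity = significant calls with the expected direction, divided by
#' the reference miRNAs present in the tested panel; accuracy uses the full
#' reference length as denominator. Both denominators are reported.
#'
#' @param de a [wilcoxon_de()] table (direction = `up` means higher in group
#'   A).
#' @param reference data.frame with columns `mirna` and `direction`
#'   (`"up"`/`"down"`, the expected group-A-vs-group-B direction).
#' @return list with `sensitivity`, `accuracy`, `n_present`,
#'   `n_reference`, `n_correct` and `concordance` (per-miRNA table).
#' @export
sensitivity_vs_reference <- function(de, reference) {
  if (!nrow(reference)) stop("reference list is empty")
  stopifnot(all(c("mirna", "direction") %in% names(reference)))
  present <- reference$mirna %in% de$mirna
  if (!any(present)) {
    warning("no overlap between the reference and the tested panel")
    return(list(sensitivity = 0, accuracy = 0, n_present = 0L,
                n_reference = nrow(reference), n_correct = 0L,
                concordance = data.frame()))
  }
  ref <- reference[present, , drop = FALSE]
  idx <- match(ref$mirna, de$mirna)
  called <- de$significant[idx]
  same_dir <- de$direction[idx] == ref$direction
  correct <- called & same_dir
  concordance <- data.frame(mirna = ref$mirna,
                            expected = ref$direction,
                            observed = de$direction[idx],
                            significant = called,
                            correct = correct, row.names = NULL)
  list(sensitivity = sum(correct) / nrow(ref),
       accuracy = sum(correct) / nrow(reference),
       n_present = nrow(ref), n_reference = nrow(reference),
       n_correct = sum(correct), concordance = concordance)
}

#' Odds ratio and Fisher exact test for a 2x2 contingency table
#'
#' Sample odds ratio `(a d)/(b c)` with a two-sided Fisher exact p-value and
#' a Wald-type confidence interval on the log odds ratio. Zero cells trigger
#' the Haldane-Anscombe correction (+0.5 to every cell, flagged).
#'
#' @param a,b,c,d nonnegative integer cell counts; rows are the two groups,
#'   columns the outcome (`a`/`b` = group 1 outcome yes/no, `c`/`d` =
#'   group 2).
#' @param conf_level confidence level (default 0.95).
#' @return list with `odds_ratio`, `p_value`, `conf_int` (length-2),
#'   `haldane` (correction flag) and the `table`.
#' @export
#' @examples
#' contingency_odds_ratio(1, 1, 1, 1)$odds_ratio # 1
contingency_odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  check_that(all(cells >= 0) && all(cells == round(cells)),
             "cell counts must be nonnegative integers")
  tab <- matrix(cells, 2L, 2L, byrow = TRUE)
  haldane <- any(cells == 0)
  w <- if (haldane) cells + 0.5 else cells
  or <- (w[1L] * w[4L]) / (w[2L] * w[3L])
  se <- sqrt(sum(1 / w))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zq * se)
  p <- fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, conf_int = ci, haldane = haldane,
       table = tab)
}

#' Proportions and fold changes from summary counts
#'
#' Small arithmetic helpers for contingency summaries: percentage of a count
#' within a denominator, and the fold change between two counts, both rounded
#' to one decimal by default.
#'
#' @param k,n count and denominator for `proportion_pct`.
#' @param num,den numerator and denominator counts for `fold_change`.
#' @param digits rounding (default 1 decimal).
#' @return a single rounded numeric value.
#' @export
#' @examples
#' proportion_pct(1, 4)  # 25
#' fold_change(10, 10)   # 1
proportion_pct <- function(k, n, digits = 1L) {
  check_that(n > 0, "zero denominator")
  round(100 * k / n, digits)
}

#' @rdname proportion_pct
#' @export
fold_change <- function(num, den, digits = 1L) {
  check_that(den > 0, "zero denominator")
  round(num / den, digits)
}
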