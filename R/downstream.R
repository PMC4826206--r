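## Downstream subtype characterisation: between-subtype differential
## expression by rank-sum test with fold-change filtering, miRNA target
## lookup against an evidence table, and per-gene copy-number versus
## expression one-way ANOVA.

#' Between-subtype differential feature analysis
#'
#' Per feature: a two-sided Wilcoxon rank-sum p-value comparing the two
#' subtypes (exact when the combined sample size is at most 20, otherwise
#' the normal approximation with tie correction) and the fold change of
#' subtype 2 over subtype 1. On the linear scale the fold change is the
#' ratio of group means; when `log2_input = TRUE` it is
#' `2^(mean2 - mean1)`.
#'
#' @param expr Patients-by-features matrix.
#' @param labels Named vector (patient to subtype) or `subtype_assignment`;
#'   exactly two subtypes, each with at least two patients.
#' @param log2_input Is the expression matrix on the log2 scale?
#' @return Data frame with `feature`, `p`, `fold_change`, `direction`
#'   (`"up"` when subtype 2 exceeds subtype 1).
#' @export
differential_features <- function(expr, labels, log2_input = FALSE) {
  if (inherits(labels, "subtype_assignment")) labels <- labels$labels
  grp <- labels[rownames(expr)]
  if (any(is.na(grp))) stopf("every patient in 'expr' needs a label")
  lev <- sort(unique(grp))
  if (length(lev) != 2L) stopf("pairwise only: need exactly 2 subtypes")
  g1 <- rownames(expr)[grp == lev[1L]]
  g2 <- rownames(expr)[grp == lev[2L]]
  if (length(g1) < 2L || length(g2) < 2L) {
    stopf("each subtype needs >= 2 patients")
  }
  exact <- (length(g1) + length(g2)) <= 20L
  res <- vapply(seq_len(ncol(expr)), function(j) {
    x1 <- expr[g1, j]
    x2 <- expr[g2, j]
    p <- suppressWarnings(stats::wilcox.test(x2, x1, exact = exact)$p.value)
    m1 <- mean(x1)
    m2 <- mean(x2)
    fc <- if (log2_input) 2^(m2 - m1) else m2 / m1
    c(p = min(p, 1), fc = fc)
  }, c(p = 0, fc = 0))
  data.frame(feature = colnames(expr), p = res["p", ],
             fold_change = res["fc", ],
             direction = ifelse(res["fc", ] > 1, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter differential results to upregulated features
#'
#' Keeps features with `p < p_cut` and `fold_change > fc_cut`, both strict.
#'
#' @param results Data frame from [differential_features()].
#' @param p_cut P-value cutoff (default 0.01).
#' @param fc_cut Fold-change cutoff (default 1.2).
#' @return The qualifying subset of `results`.
#' @export
filter_upregulated <- function(results, p_cut = 0.01, fc_cut = 1.2) {
  keep <- results$p < p_cut & results$fold_change > fc_cut
  results[keep, , drop = FALSE]
}

#' miRNAs targeting a gene at a given evidence tier
#'
#' @param gene Target gene id.
#' @param table Target table with columns `mirna`, `gene`, `evidence`.
#' @param tier Evidence tier to require (default `"strong"`).
#' @return Character vector of unique miRNA ids.
#' @export
mirnas_targeting <- function(gene, table, tier = "strong") {
  unique(table$mirna[table$gene == gene & table$evidence == tier])
}

#' Intersect upregulated and targeting miRNA sets
#'
#' @param upregulated Character vector of upregulated miRNA ids.
#' @param targeting Character vector of miRNAs targeting the gene of
#'   interest.
#' @return The intersection (unique ids).
#' @export
intersect_candidates <- function(upregulated, targeting) {
  intersect(unique(upregulated), unique(targeting))
}

#' One-way ANOVA of expression across copy-number categories
#'
#' Fixed-effects F test of whether a gene's expression differs across its
#' copy-number call categories.
#'
#' @param expr_values Numeric expression values, one per patient.
#' @param cn_category Copy-number category per patient (same length).
#' @return List with `f_statistic`, `df`, `p_value`.
#' @export
cna_expression_anova <- function(expr_values, cn_category) {
  if (length(expr_values) != length(cn_category)) {
    stopf("'expr_values' and 'cn_category' must have the same length")
  }
  f <- factor(cn_category)
  tab <- table(f)
  if (length(tab) < 2L) stopf("need >= 2 copy-number categories")
  if (any(tab < 2L)) stopf("every category needs >= 2 patients")
  if (diff(range(expr_values)) == 0) {
    stopf("degenerate input: no within- or between-category variance")
  }
  fit <- stats::lm(expr_values ~ f)
  an <- suppressWarnings(stats::anova(fit))
  fs <- an[["F value"]][1L]
  if (is.na(fs)) {
    stopf("degenerate input: no within- or between-category variance")
  }
  ## perfect separation gives F = Inf; keep p strictly positive
  p <- an[["Pr(>F)"]][1L]
  list(f_statistic = fs, df = unname(an[["Df"]][1:2]),
       p_value = max(p, .Machine$double.xmin))
}
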