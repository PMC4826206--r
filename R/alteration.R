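## Copy-number alteration scoring: binarize GISTIC-style gene-level calls,
## compute sample-weighted per-gene alteration scores within a subtype, and
## threshold them into the subtype's altered-gene set.

#' Binarize gene-level copy-number calls
#'
#' Only high-level events count as alterations: a gene/sample cell becomes 1
#' iff its call is -2 (homozygous deletion) or +2 (high amplification);
#' shallow losses and single-copy gains (-1, +1) and neutral calls are 0.
#'
#' @param calls Integer matrix of codes in -2..2, genes in rows, samples in
#'   columns.
#' @return Binary matrix of the same shape.
#' @export
binarize_copy_number <- function(calls) {
  check_gistic_codes(calls)
  x <- (abs(calls) == 2) * 1L
  dimnames(x) <- dimnames(calls)
  x
}

#' Sample-weighted gene alteration scores within a subtype
#'
#' Restricted to the subtype's samples, each sample's alterations are first
#' normalised by that sample's total alteration count, so that an alteration
#' observed in a quiet genome carries more weight than one in a heavily
#' altered genome. The gene score is the row sum of the normalised matrix,
#' \eqn{C_i = \sum_j x_{ij} / \sum_i x_{ij}}, and the normalised score is
#' \eqn{p^0_i = C_i / \sum_i C_i}, which sums to one over genes. Samples
#' with no alterations contribute nothing (they are skipped, not divided
#' by zero).
#'
#' @param x Binary genes-by-samples alteration matrix.
#' @param subtype_samples Character vector of sample ids in the subtype.
#' @return Data frame with columns `gene`, `score` (\eqn{C_i}) and `p0`.
#' @export
gene_alteration_scores <- function(x, subtype_samples = colnames(x)) {
  if (length(subtype_samples) == 0L) stopf("'subtype_samples' is empty")
  missing_s <- setdiff(subtype_samples, colnames(x))
  if (length(missing_s) > 0L) {
    stopf("sample(s) not in alteration matrix: %s",
          paste(missing_s, collapse = ", "))
  }
  if (!all(x %in% c(0L, 1L))) stopf("alteration matrix must be binary")
  sub <- x[, subtype_samples, drop = FALSE]
  csum <- colSums(sub)
  if (all(csum == 0)) stopf("no alterations in subtype")
  keep <- csum > 0
  weighted <- sweep(sub[, keep, drop = FALSE], 2L, csum[keep], `/`)
  ci <- rowSums(weighted)
  data.frame(gene = rownames(x), score = unname(ci),
             p0 = unname(ci / sum(ci)), stringsAsFactors = FALSE)
}

#' Threshold gene scores into an altered-gene set
#'
#' Keeps genes whose normalised score `p0` is at least `tau` (boundary
#' inclusive).
#'
#' @param scores Data frame from [gene_alteration_scores()].
#' @param tau Nonnegative threshold on `p0` (default 2e-4).
#' @return Character vector of altered gene ids, with attribute
#'   `threshold`.
#' @export
filter_altered_genes <- function(scores, tau = 2e-4) {
  check_scalar(tau, "tau", lower = 0)
  genes <- scores$gene[scores$p0 >= tau]
  structure(genes, threshold = tau)
}
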