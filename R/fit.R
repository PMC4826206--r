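## The model-object front end: fit integrative subtypes from a list of
## omics views (plus survival data) in one call, returning a classed object
## with the usual methods.

#' Fit integrative patient subtypes from multiple omics views
#'
#' Aligns the views (and clinical table) to their common patients, fuses the
#' per-view patient similarity networks by similarity network fusion, and
#' clusters the fused network by spectral clustering. When a clinical table
#' is supplied, the number of subtypes is chosen from `c_range` by the
#' minimal log-rank p-value across candidate clusterings; otherwise
#' `n_subtypes` must be given.
#'
#' @param views List (>= 2) of patients-by-features matrices.
#' @param clinical Optional clinical data frame with `patient_id`,
#'   `os_time`, `os_event`.
#' @param n_subtypes Fixed number of subtypes (used when `clinical` is
#'   absent, or to bypass selection).
#' @param c_range Candidate subtype counts for survival-guided selection.
#' @param mu Affinity kernel bandwidth multiplier.
#' @param k Neighbourhood size (`NULL` for the default, ceiling(n/10)
#'   clamped to 10..30).
#' @param t_iter Fusion iterations.
#' @param seed RNG seed for the clustering restarts.
#' @return An object of class `snf_subtype`: list with `fused`
#'   (`fused_network`), `assignment` (`subtype_assignment`), `labels`,
#'   `selection` (per-candidate log-rank table, or `NULL`), `logrank`,
#'   `clinical`, `call`.
#' @export
snf_subtype <- function(views, clinical = NULL, n_subtypes = NULL,
                        c_range = 2:5, mu = 0.5, k = NULL, t_iter = 20L,
                        seed = 1L) {
  cl <- match.call()
  if (is.null(clinical) && is.null(n_subtypes)) {
    stopf("either 'clinical' (for survival-guided selection) or 'n_subtypes' is required")
  }
  aligned <- suppressMessages(align_cohort(views, clinical))
  fused <- fuse_views(aligned$views, mu = mu, k = k, t_iter = t_iter)
  if (is.null(n_subtypes)) {
    sel <- select_cluster_number(fused, aligned$clinical, c_range, seed)
    assignment <- sel$assignment
    selection <- sel$selection
  } else {
    assignment <- spectral_clusters(fused, n_subtypes, seed = seed)
    selection <- NULL
  }
  lr <- if (!is.null(aligned$clinical) && assignment$n_clusters >= 2L) {
    logrank_test(aligned$clinical, assignment)
  }
  structure(list(fused = fused, assignment = assignment,
                 labels = assignment$labels, selection = selection,
                 logrank = lr, clinical = aligned$clinical, call = cl),
            class = "snf_subtype")
}

#' @export
print.snf_subtype <- function(x, ...) {
  cat("Integrative subtype model (similarity network fusion)\n")
  cat(sprintf("  patients: %d   views: %d   subtypes: %d\n",
              length(x$labels), x$fused$n_views,
              x$assignment$n_clusters))
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank: chi-square %.3f on %d df, p = %.3g\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p_value))
  }
  invisible(x)
}

#' @export
summary.snf_subtype <- function(object, ...) {
  print(object)
  cat("\nSubtype sizes:\n")
  print(table(subtype = object$labels))
  if (!is.null(object$selection)) {
    cat("\nSurvival-guided selection (log-rank per candidate count):\n")
    print(object$selection, row.names = FALSE)
  }
  invisible(object)
}

#' Kaplan-Meier plot of the fitted subtypes
#'
#' @param x A fitted `snf_subtype` with a clinical table.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.snf_subtype <- function(x, ...) {
  if (is.null(x$clinical)) stopf("no clinical data in the fit")
  grp <- factor(x$labels[x$clinical$patient_id])
  fit <- survival::survfit(
    survival::Surv(os_time, os_event) ~ grp,
    data = data.frame(x$clinical, grp = grp))
  graphics::plot(fit, col = seq_len(nlevels(grp)), xlab = "Time (days)",
                 ylab = "Overall survival", ...)
  graphics::legend("topright", legend = paste("Subtype", levels(grp)),
                   col = seq_len(nlevels(grp)), lty = 1, bty = "n")
  invisible(x)
}

#' Subtype labels of a fitted model
#'
#' @param fit A fitted `snf_subtype`.
#' @return Named integer vector, patient to subtype.
#' @export
subtype_labels <- function(fit) {
  stopifnot(inherits(fit, "snf_subtype"))
  fit$labels
}
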