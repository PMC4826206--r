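## Subtype discovery: spectral clustering of the fused similarity network
## via the normalized Laplacian, Kaplan-Meier curves, the log-rank test, and
## survival-guided selection of the number of subtypes.

#' Spectral clustering of a fused similarity network
#'
#' Forms the normalised Laplacian `L = I - D^{-1/2} W D^{-1/2}` of the fused
#' similarity matrix, takes the eigenvectors belonging to its `n_clusters`
#' smallest eigenvalues, row-normalises them to unit length and partitions
#' the rows by k-means with multiple restarts (the standard relaxation of
#' the trace-minimisation objective over scaled partition matrices).
#' Cluster labels are canonical: clusters are numbered by decreasing size,
#' ties broken by the smallest patient id they contain.
#'
#' A disconnected fused graph is handled naturally: each connected component
#' contributes a zero eigenvalue whose indicator eigenvector separates it in
#' the embedding.
#'
#' @param fused A `fused_network` object or a symmetric nonnegative matrix
#'   with patient dimnames.
#' @param n_clusters Number of clusters, `2 <= n_clusters <= n`.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return An object of class `subtype_assignment`: list with `labels`
#'   (named integer vector in 1..C), `n_clusters`, `q` (the scaled partition
#'   matrix `Y (Y'Y)^{-1/2}`) and `embedding`.
#' @export
spectral_clusters <- function(fused, n_clusters, seed = 1L, nstart = 50L) {
  w <- if (inherits(fused, "fused_network")) fused$w else fused
  n <- nrow(w)
  check_scalar(n_clusters, "n_clusters", lower = 1, upper = n,
               integer = TRUE)
  deg <- rowSums(w)
  if (any(deg <= 0)) stopf("fused matrix has a zero-degree patient")
  if (n_clusters == n) {
    ## every patient its own subtype: the relaxation is exact and k-means
    ## degenerates, so assign singletons directly (canonical order by id)
    labels <- stats::setNames(rank(rownames(w), ties.method = "first"),
                              rownames(w))
    return(structure(list(labels = labels, n_clusters = as.integer(n),
                          q = diag(n), embedding = diag(n),
                          eigenvalues = rep(NA_real_, n)),
                     class = "subtype_assignment"))
  }
  d_half <- 1 / sqrt(deg)
  lap <- diag(n) - (d_half * w) %*% diag(d_half)
  lap <- (lap + t(lap)) / 2
  eig <- eigen(lap, symmetric = TRUE)
  ## eigen() sorts decreasing; the smallest n_clusters are the last columns
  u <- eig$vectors[, n - seq_len(n_clusters) + 1L, drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  ## suppress Hartigan-Wong's non-convergence warning: when the embedding is
  ## effectively lower-rank than n_clusters (more clusters requested than the
  ## graph supports) individual starts may cycle; the multiple restarts still
  ## return the best partition found
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(u, centers = n_clusters, nstart = nstart,
                  iter.max = 100L)))
  labels <- km$cluster
  names(labels) <- rownames(w)
  labels <- canonicalize_labels(labels)
  y <- outer(labels, seq_len(n_clusters), `==`) * 1
  q <- y %*% diag(1 / sqrt(colSums(y)), n_clusters)
  structure(list(labels = labels, n_clusters = as.integer(n_clusters),
                 q = q, embedding = u, eigenvalues = rev(eig$values)),
            class = "subtype_assignment")
}

## Relabel clusters 1..C by decreasing size, ties by smallest member id.
canonicalize_labels <- function(labels) {
  sizes <- table(labels)
  first_id <- vapply(names(sizes),
                     function(l) min(names(labels)[labels == l]), "")
  ord <- order(-as.integer(sizes), first_id, method = "radix")
  new <- integer(length(sizes))
  new[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  out <- new[labels]
  names(out) <- names(labels)
  out
}

#' Kaplan-Meier survival curve for a patient group
#'
#' Product-limit estimator evaluated at each distinct event time of the
#' group.
#'
#' @param clinical Clinical data frame with `patient_id`, `os_time`,
#'   `os_event`.
#' @param group Character vector of patient ids (default: all patients).
#' @return Data frame with columns `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(clinical, group = clinical$patient_id) {
  if (length(group) == 0L) stopf("empty patient group")
  clin <- validate_clinical(clinical)
  sub <- clin[clin$patient_id %in% group, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("no clinical rows for the requested group")
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ 1, data = sub)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep], surv = fit$surv[keep])
}

#' Log-rank test between patient subtypes
#'
#' Standard (Mantel-Haenszel / score) log-rank chi-square comparing the
#' survival distributions of two or more groups, with `C - 1` degrees of
#' freedom. This coincides with the Cox partial-likelihood score test for a
#' group factor, so no separate Cox model is fit.
#'
#' @param clinical Clinical data frame.
#' @param labels Named vector (patient to group) or a `subtype_assignment`.
#' @return List with `chisq`, `df` and `p_value`.
#' @export
logrank_test <- function(clinical, labels) {
  if (inherits(labels, "subtype_assignment")) labels <- labels$labels
  clin <- validate_clinical(clinical)
  grp <- labels[clin$patient_id]
  if (any(is.na(grp))) stopf("every patient needs a subtype label")
  tab <- table(grp)
  if (length(tab) < 2L) stopf("need >= 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ grp,
                           data = data.frame(clin, grp = factor(grp)))
  df <- length(tab) - 1L
  chisq <- unname(sd$chisq)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Survival-guided choice of the number of subtypes
#'
#' Clusters the fused network for every candidate cluster count, computes
#' the log-rank p-value across the resulting groups, and returns the count
#' with the minimal p-value (ties broken in favour of the smaller count).
#'
#' @param fused A `fused_network` or fused similarity matrix.
#' @param clinical Clinical data frame covering the fused patients.
#' @param c_range Candidate cluster counts (each >= 2).
#' @param seed RNG seed forwarded to [spectral_clusters()].
#' @return List with `best_c`, `assignment` (for `best_c`), and `selection`
#'   (data frame of `n_clusters`, `chisq`, `p_value`).
#' @export
select_cluster_number <- function(fused, clinical, c_range = 2:5,
                                  seed = 1L) {
  if (length(c_range) == 0L) stopf("'c_range' must be non-empty")
  c_range <- sort(unique(as.integer(c_range)))
  fits <- lapply(c_range, function(cc)
    spectral_clusters(fused, cc, seed = seed))
  tests <- lapply(fits, function(f) logrank_test(clinical, f))
  sel <- data.frame(n_clusters = c_range,
                    chisq = vapply(tests, `[[`, 0, "chisq"),
                    p_value = vapply(tests, `[[`, 0, "p_value"))
  best <- which.min(sel$p_value)  # which.min takes the first, i.e. smaller C
  list(best_c = c_range[best], assignment = fits[[best]], selection = sel)
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("Subtype assignment: %d patients in %d clusters\n",
              length(x$labels), x$n_clusters))
  print(table(subtype = x$labels))
  invisible(x)
}
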