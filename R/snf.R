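## Similarity network fusion: per-view scaled-exponential affinity kernels,
## full and k-nearest-neighbour transition kernels, and the iterative
## cross-diffusion that fuses the views into one patient similarity network.

#' Pairwise Euclidean distances between patients
#'
#' @param x Numeric patients-by-features matrix (no missing values).
#' @return Symmetric distance matrix with zero diagonal and patient
#'   dimnames.
#' @export
euclidean_distances <- function(x) {
  if (any(!is.finite(x))) stopf("feature matrix contains non-finite values")
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  diag(d) <- 0
  d
}

## k nearest neighbours of each row of a distance matrix, self excluded;
## ties broken by (distance, patient-id) lexicographic order.
knn_index <- function(d, k) {
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  res <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], ids, method = "radix")
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k))
  matrix(res, nrow = n, ncol = k, byrow = TRUE)
}

#' Scaled exponential affinity kernel
#'
#' Affinity between patients i and j is
#' `W(i,j) = exp(-d(i,j)^2 / (mu * eps(i,j)))`, where the local scale
#' `eps(i,j)` is the mean of (i) the average distance from i to its k
#' nearest neighbours, (ii) the same for j, and (iii) `d(i,j)` itself.
#' Neighbourhoods exclude self (a zero self-distance would deflate the
#' scale).
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param mu Positive bandwidth multiplier.
#' @param k Neighbourhood size, `0 < k <= n - 1`.
#' @return Symmetric affinity matrix with unit diagonal, entries in (0, 1].
#' @export
scaled_affinity <- function(d, mu = 0.5, k = 20L) {
  n <- nrow(d)
  check_scalar(mu, "mu", lower = 0, open_lower = TRUE)
  check_scalar(k, "k", lower = 1, upper = n - 1, integer = TRUE)
  nn <- knn_index(d, k)
  mean_nn <- vapply(seq_len(n), function(i) mean(d[i, nn[i, ]]), 0)
  eps <- (outer(mean_nn, mean_nn, "+") + d) / 3
  eps[eps <= 0] <- .Machine$double.eps
  w <- exp(-(d^2) / (mu * eps))
  w <- (w + t(w)) / 2
  diag(w) <- 1
  dimnames(w) <- dimnames(d)
  w
}

#' Full transition kernel
#'
#' Row-normalises an affinity matrix so that each off-diagonal entry is
#' `W(i,j) / (2 * sum_{k != i} W(i,k))` and each diagonal entry is exactly
#' 1/2; every row then sums to one. The normalisation ignores the diagonal
#' self-similarity scale.
#'
#' @param w Symmetric affinity matrix with positive off-diagonal row sums.
#' @return Row-stochastic transition matrix with diagonal 1/2.
#' @export
full_kernel <- function(w) {
  n <- nrow(w)
  if (n < 2L) stopf("need at least 2 patients")
  ## sum the off-diagonal entries directly: subtracting the unit diagonal
  ## from the row sum would cancel catastrophically when affinities are tiny
  w_off <- w
  diag(w_off) <- 0
  off <- rowSums(w_off)
  if (any(off <= 0)) {
    stopf("row %d has zero off-diagonal affinity mass", which(off <= 0)[1L])
  }
  p <- w / (2 * off)
  diag(p) <- 0.5
  dimnames(p) <- dimnames(w)
  p
}

#' Local (k-nearest-neighbour) kernel
#'
#' Keeps, for each patient, only the affinities to its k nearest neighbours
#' (by distance, self excluded, ties broken by patient id) and normalises
#' each row to sum to one; all other entries, including the diagonal, are
#' zero.
#'
#' @param d Distance matrix used to define the neighbourhoods.
#' @param w Matching affinity matrix.
#' @param k Neighbourhood size, `0 < k <= n - 1`.
#' @return Sparse-in-structure row-stochastic matrix with exactly k nonzero
#'   entries per row.
#' @export
local_kernel <- function(d, w, k = 20L) {
  n <- nrow(w)
  check_scalar(k, "k", lower = 1, upper = n - 1, integer = TRUE)
  nn <- knn_index(d, k)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    wi <- w[i, nn[i, ]]
    s[i, nn[i, ]] <- wi / sum(wi)
  }
  s
}

## Re-impose the transition-kernel invariants (symmetry, diagonal 1/2,
## row-stochastic) after a diffusion step.
renormalize_status <- function(p) {
  p <- (p + t(p)) / 2
  p_off <- p
  diag(p_off) <- 0
  off <- rowSums(p_off)
  off[off <= 0] <- .Machine$double.eps
  p <- p / (2 * off)
  diag(p) <- 0.5
  (p + t(p)) / 2
}

#' Fuse per-view similarity networks by cross-diffusion
#'
#' Runs `t_iter` synchronous updates in which each view's status matrix is
#' replaced by `S_v %*% mean(other status matrices) %*% t(S_v)`, where `S_v`
#' is the view's local kernel. After every update each status matrix is
#' symmetrised and re-normalised to the transition-kernel form (the raw
#' update does not preserve row-stochasticity). The fused network is the
#' arithmetic mean of the final status matrices, symmetrised.
#'
#' @param p_list List of full transition kernels, one per view (>= 2).
#' @param s_list List of matching local kernels, index-aligned with
#'   `p_list`.
#' @param t_iter Number of fusion iterations.
#' @return An object of class `fused_network`: list with `w` (fused
#'   matrix), `n_views`, `iterations`, `last_change` (max relative change of
#'   the fused average at the final step).
#' @export
snf_fuse <- function(p_list, s_list, t_iter = 20L) {
  m <- length(p_list)
  if (m < 2L) stopf("fusion needs >= 2 views")
  if (length(s_list) != m) stopf("'p_list' and 's_list' must be index-aligned")
  n <- nrow(p_list[[1L]])
  for (x in c(p_list, s_list)) {
    if (!all(dim(x) == c(n, n))) stopf("all matrices must be %d x %d", n, n)
  }
  check_scalar(t_iter, "t_iter", lower = 1, integer = TRUE)
  p <- p_list
  fused_prev <- Reduce(`+`, p) / m
  last_change <- NA_real_
  for (it in seq_len(t_iter)) {
    p_new <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, p[-v]) / (m - 1)
      p_new[[v]] <- renormalize_status(s_list[[v]] %*% others %*%
                                         t(s_list[[v]]))
    }
    p <- p_new
    fused <- Reduce(`+`, p) / m
    last_change <- max(abs(fused - fused_prev)) /
      max(abs(fused_prev), .Machine$double.eps)
    fused_prev <- fused
  }
  fused <- (fused_prev + t(fused_prev)) / 2
  dimnames(fused) <- dimnames(p_list[[1L]])
  structure(list(w = fused, n_views = m, iterations = as.integer(t_iter),
                 last_change = last_change),
            class = "fused_network")
}

#' @export
print.fused_network <- function(x, ...) {
  cat(sprintf("Fused patient similarity network: %d patients, %d views, %d iterations\n",
              nrow(x$w), x$n_views, x$iterations))
  cat(sprintf("max relative change at last step: %.3g\n", x$last_change))
  invisible(x)
}

## Default neighbourhood size: ceiling(n/10) clamped to [10, 30], or n - 1
## for very small cohorts.
default_snf_k <- function(n) {
  k <- min(max(ceiling(n / 10), 10L), 30L)
  min(k, n - 1L)
}

#' Build affinity kernels and fuse a list of views
#'
#' Convenience wrapper: computes distances, scaled affinities and both
#' kernels per view, then runs [snf_fuse()].
#'
#' @param views List (>= 2) of patients-by-features matrices over identical
#'   patients.
#' @param mu Kernel bandwidth multiplier.
#' @param k Neighbourhood size; `NULL` for the default
#'   ceiling(n/10) clamped to 10..30.
#' @param t_iter Fusion iterations.
#' @return A `fused_network` object.
#' @export
fuse_views <- function(views, mu = 0.5, k = NULL, t_iter = 20L) {
  if (length(views) < 2L) stopf("fusion needs >= 2 views")
  ids <- rownames(views[[1L]])
  for (v in views) {
    if (!identical(rownames(v), ids)) {
      stopf("all views must share the same patients in the same order")
    }
  }
  n <- nrow(views[[1L]])
  if (is.null(k)) k <- default_snf_k(n)
  d_list <- lapply(views, euclidean_distances)
  w_list <- lapply(d_list, scaled_affinity, mu = mu, k = k)
  p_list <- lapply(w_list, full_kernel)
  s_list <- mapply(local_kernel, d_list, w_list,
                   MoreArgs = list(k = k), SIMPLIFY = FALSE)
  snf_fuse(p_list, s_list, t_iter = t_iter)
}
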