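## Altered-network module detection: subnetwork extraction around altered
## genes, hypergeometric linker-gene significance with BH correction,
## greedy Newman-modularity agglomeration, and the two null models
## (degree-preserving rewiring for modularity, random gene sets for global
## connectivity).

#' Extract the altered subnetwork and nominate candidate linker genes
#'
#' Keeps the direct interactions among altered genes and nominates as
#' candidate linkers every non-altered gene adjacent to at least two altered
#' genes (i.e. lying on a path of length two between a pair of altered
#' genes). Altered genes absent from the network are dropped with a message.
#'
#' @param net Undirected simple igraph with named vertices.
#' @param altered Character vector of altered gene ids.
#' @param path_threshold Maximum path length through a linker; only the
#'   value 2 (one intermediate gene) is supported.
#' @return List with `altered` (present altered genes), `candidates`
#'   (candidate linker ids), `altered_neighbors` (named count of altered
#'   neighbours per candidate) and `altered_graph` (induced graph on the
#'   altered genes).
#' @export
extract_subnetwork <- function(net, altered, path_threshold = 2L) {
  if (length(altered) == 0L) stopf("'altered' is empty")
  if (path_threshold != 2L) stopf("only path_threshold = 2 is supported")
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) stopf("network vertices must be named")
  present <- intersect(altered, nodes)
  dropped <- length(unique(altered)) - length(present)
  if (dropped > 0L) {
    message(sprintf("dropped %d altered gene(s) absent from the network",
                    dropped))
  }
  if (length(present) == 0L) stopf("no altered genes present in the network")
  n <- length(nodes)
  alt_idx <- match(present, nodes)
  is_alt <- logical(n)
  is_alt[alt_idx] <- TRUE
  nb <- igraph::adjacent_vertices(net, alt_idx)
  cnt <- tabulate(as.integer(unlist(nb)), nbins = n)
  cand_idx <- which(!is_alt & cnt >= 2L)
  list(altered = present,
       candidates = nodes[cand_idx],
       altered_neighbors = stats::setNames(cnt[cand_idx], nodes[cand_idx]),
       altered_graph = igraph::induced_subgraph(net, alt_idx))
}

#' Hypergeometric linker-gene significance
#'
#' Upper-tail probability of observing at least the candidate's number of
#' altered neighbours when its `d` neighbours are drawn without replacement
#' from the `N - 1` other genes, of which `K` are altered.
#'
#' @param net Undirected igraph with named vertices.
#' @param altered Character vector of altered gene ids.
#' @param candidate A single non-altered gene id with degree >= 1.
#' @return Raw p-value in (0, 1].
#' @export
linker_significance <- function(net, altered, candidate) {
  nodes <- igraph::V(net)$name
  if (!candidate %in% nodes) stopf("candidate '%s' not in network", candidate)
  if (candidate %in% altered) stopf("candidate '%s' is itself altered",
                                    candidate)
  d <- igraph::degree(net, candidate)
  if (d < 1L) stopf("candidate '%s' has degree 0", candidate)
  present <- intersect(altered, nodes)
  nb <- names(igraph::neighbors(net, candidate))
  k <- sum(nb %in% present)
  n_tot <- igraph::vcount(net)
  stats::phyper(k - 1L, length(present), n_tot - 1L - length(present), d,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values, order-preserving with the input.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise >= the raw ones.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Build a subtype-specific altered network with significant linkers
#'
#' Candidate linkers (from [extract_subnetwork()]) are scored by the
#' hypergeometric enrichment test, BH-adjusted, and admitted when the
#' adjusted p-value is at most `alpha`. The final network is the induced
#' graph on the altered genes plus the admitted linkers, restricted to genes
#' with at least one edge.
#'
#' @param net Undirected igraph with named vertices.
#' @param altered Character vector of altered gene ids.
#' @param alpha BH-adjusted p cutoff in (0, 1].
#' @param path_threshold See [extract_subnetwork()].
#' @return List of class `subtype_network` with `graph`, `altered_nodes`,
#'   `linker_nodes` and `linker_table` (gene, degree, altered_neighbors,
#'   p, p_adj).
#' @export
build_subtype_network <- function(net, altered, alpha = 0.05,
                                  path_threshold = 2L) {
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  ex <- extract_subnetwork(net, altered, path_threshold)
  n_tot <- igraph::vcount(net)
  k_alt <- length(ex$altered)
  if (length(ex$candidates) > 0L) {
    d <- igraph::degree(net, ex$candidates)
    k <- ex$altered_neighbors[ex$candidates]
    p <- stats::phyper(k - 1L, k_alt, n_tot - 1L - k_alt, d,
                       lower.tail = FALSE)
    p_adj <- bh_adjust(p)
    linker_table <- data.frame(gene = ex$candidates, degree = unname(d),
                               altered_neighbors = unname(k),
                               p = unname(p), p_adj = unname(p_adj),
                               stringsAsFactors = FALSE)
    linkers <- ex$candidates[p_adj <= alpha]
  } else {
    linker_table <- data.frame(gene = character(), degree = integer(),
                               altered_neighbors = integer(), p = numeric(),
                               p_adj = numeric(), stringsAsFactors = FALSE)
    linkers <- character()
  }
  keep <- c(ex$altered, linkers)
  g <- igraph::induced_subgraph(net, keep)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  in_g <- igraph::V(g)$name
  structure(list(graph = g,
                 altered_nodes = intersect(ex$altered, in_g),
                 linker_nodes = intersect(linkers, in_g),
                 linker_table = linker_table),
            class = "subtype_network")
}

#' Newman modularity of a partition
#'
#' \eqn{Q = \sum_c [e_c/E - (d_c/2E)^2]} where `E` is the number of edges,
#' `e_c` the number of intra-community edges and `d_c` the total degree of
#' community `c`. The partition must cover every non-isolated node.
#'
#' @param graph Undirected simple igraph with named vertices.
#' @param membership Named vector mapping each non-isolated node to its
#'   community.
#' @return Modularity value in \[-1/2, 1\].
#' @export
modularity_q <- function(graph, membership) {
  e_tot <- igraph::ecount(graph)
  if (e_tot == 0L) stopf("modularity is undefined on an empty edge set")
  deg <- igraph::degree(graph)
  non_iso <- names(deg)[deg > 0]
  if (!setequal(names(membership), non_iso)) {
    stopf("partition must cover exactly the non-isolated nodes")
  }
  q <- 0
  for (comm in unique(membership)) {
    mem <- names(membership)[membership == comm]
    e_c <- igraph::ecount(igraph::induced_subgraph(graph, mem))
    d_c <- sum(deg[mem])
    q <- q + e_c / e_tot - (d_c / (2 * e_tot))^2
  }
  q
}

#' Detect modules by greedy modularity-maximising agglomeration
#'
#' Starts from singleton communities on the non-isolated nodes and
#' repeatedly merges the edge-connected community pair giving the largest
#' modularity gain (ties broken by the lexicographically smallest pair of
#' community representatives, a representative being the community's
#' smallest gene id), recording the partition after every merge. Because
#' only edge-connected pairs are merged, connected components are never
#' merged across. The highest-modularity partitions along the merge
#' sequence (the top `n_refine`) are then each polished by a deterministic
#' single-node move pass -- a node may hop to a community holding one of
#' its neighbours, or out into its own, whenever that strictly increases
#' modularity -- and the best refined partition is returned.
#'
#' @param subnet A `subtype_network` (its graph is used) or an igraph.
#' @param n_refine How many of the best merge-sequence partitions to
#'   refine.
#' @return List of class `module_partition` with `modules` (list of node
#'   sets, sorted by decreasing size), `membership` (named integer vector)
#'   and `q` (modularity of the returned partition).
#' @export
detect_modules <- function(subnet, n_refine = 5L) {
  graph <- if (inherits(subnet, "subtype_network")) subnet$graph else subnet
  e_tot <- igraph::ecount(graph)
  if (e_tot == 0L) stopf("cannot detect modules in an edgeless network")
  deg_all <- igraph::degree(graph)
  g <- igraph::induced_subgraph(graph, names(deg_all)[deg_all > 0])
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  b <- igraph::as_adjacency_matrix(g, sparse = FALSE)  # diag tracks 2*e_c
  storage.mode(b) <- "double"
  d <- rowSums(b)
  members <- as.list(nodes)
  reps <- nodes
  active <- rep(TRUE, n)
  q <- -sum((d / (2 * e_tot))^2)
  snapshots <- list(list(q = q, members = members))
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    bi <- b[idx, idx, drop = FALSE]
    di <- d[idx]
    dq <- bi / e_tot - outer(di, di) / (2 * e_tot^2)
    conn <- bi > 0
    conn[lower.tri(conn, diag = TRUE)] <- FALSE
    if (!any(conn)) break
    dq[!conn] <- -Inf
    mx <- max(dq)
    cand <- which(dq >= mx - 1e-12 & conn, arr.ind = TRUE)
    ra <- pmin(reps[idx[cand[, 1L]]], reps[idx[cand[, 2L]]])
    rb <- pmax(reps[idx[cand[, 1L]]], reps[idx[cand[, 2L]]])
    pick <- order(ra, rb, method = "radix")[1L]
    a <- idx[cand[pick, 1L]]
    bb <- idx[cand[pick, 2L]]
    q <- q + b[a, bb] / e_tot - d[a] * d[bb] / (2 * e_tot^2)
    b[a, ] <- b[a, ] + b[bb, ]
    b[, a] <- b[, a] + b[, bb]
    b[bb, ] <- 0
    b[, bb] <- 0
    d[a] <- d[a] + d[bb]
    members[[a]] <- c(members[[a]], members[[bb]])
    reps[a] <- min(reps[a], reps[bb])
    active[bb] <- FALSE
    snapshots[[length(snapshots) + 1L]] <- list(q = q,
                                                members = members[active])
  }
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  qs <- vapply(snapshots, `[[`, 0, "q")
  cand <- order(-qs)[seq_len(min(n_refine, length(snapshots)))]
  best_q <- -Inf
  best_mem <- NULL
  for (ci in cand) {
    mem <- integer(n)
    names(mem) <- nodes
    ms <- snapshots[[ci]]$members
    for (i in seq_along(ms)) mem[ms[[i]]] <- i
    mem <- refine_membership(mem, adj, e_tot)
    qq <- modularity_q(g, mem)
    if (qq > best_q + 1e-12) {
      best_q <- qq
      best_mem <- mem
    }
  }
  modules <- lapply(split(nodes, best_mem), sort)
  sizes <- lengths(modules)
  firsts <- vapply(modules, `[`, "", 1L)
  modules <- modules[order(-sizes, firsts, method = "radix")]
  membership <- integer(n)
  names(membership) <- nodes
  for (i in seq_along(modules)) membership[modules[[i]]] <- i
  structure(list(modules = modules, membership = membership,
                 q = modularity_q(g, membership)),
            class = "module_partition")
}

## Deterministic single-node move refinement: visit nodes in lexicographic
## order and apply the best strictly modularity-increasing move (to a
## community holding a neighbour, or to a fresh singleton); repeat until a
## full pass makes no move.
refine_membership <- function(membership, adj, e_tot) {
  nodes <- names(membership)
  ord <- order(nodes, method = "radix")
  deg <- rowSums(adj)
  comm_deg <- tapply(deg, membership, sum)
  repeat {
    moved <- FALSE
    for (v in ord) {
      a <- membership[[v]]
      dv <- deg[[v]]
      k_to <- tapply(adj[v, ], membership, sum)
      nb_comms <- names(k_to)[k_to > 0]
      targets <- setdiff(nb_comms, as.character(a))
      ## an empty (fresh singleton) community is always a candidate
      free_id <- as.character(max(membership) + 1L)
      cand <- c(targets, free_id)
      k_va <- k_to[[as.character(a)]]
      d_a <- comm_deg[[as.character(a)]]
      dq <- vapply(cand, function(b) {
        k_vb <- if (b %in% names(k_to)) k_to[[b]] else 0
        d_b <- if (b %in% names(comm_deg)) comm_deg[[b]] else 0
        (k_vb - k_va) / e_tot - dv * (d_b - d_a + dv) / (2 * e_tot^2)
      }, 0)
      best <- which(dq >= max(dq) - 1e-12)[1L]
      if (dq[[best]] > 1e-12) {
        b <- cand[[best]]
        membership[[v]] <- as.integer(b)
        comm_deg[[as.character(a)]] <- d_a - dv
        comm_deg[[b]] <- (if (b %in% names(comm_deg)) comm_deg[[b]] else 0) + dv
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  membership
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules over %d genes, Q = %.4f\n",
              length(x$modules), length(x$membership), x$q))
  invisible(x)
}

#' Degree-preserving rewiring null distribution of modularity
#'
#' Each iteration rewires the network by attempted double-edge swaps (10
#' times the edge count), reruns [detect_modules()] on the rewired graph and
#' records the resulting modularity. Rewiring preserves every node's degree.
#' If a graph admits no swap at all, the iteration records the original
#' modularity (a single warning summarises how often this happened).
#'
#' @param subnet A `subtype_network` or igraph with at least 2 edges.
#' @param n_iter Number of null iterations (default 1000).
#' @param seed Optional RNG seed.
#' @return List of class `null_distribution` with `samples`, `mean`, `sd`,
#'   `n_iter`, `seed`.
#' @export
local_null_modularity <- function(subnet, n_iter = 1000L, seed = NULL) {
  graph <- if (inherits(subnet, "subtype_network")) subnet$graph else subnet
  if (igraph::ecount(graph) < 2L) stopf("need >= 2 edges to rewire")
  check_scalar(n_iter, "n_iter", lower = 1, integer = TRUE)
  n_swaps <- 10L * igraph::ecount(graph)
  orig_edges <- canonical_edges(graph)
  with_seed(seed, {
    n_stuck <- 0L
    samples <- vapply(seq_len(n_iter), function(i) {
      g2 <- igraph::rewire(graph, igraph::keeping_degseq(niter = n_swaps))
      stopifnot(identical(sort(igraph::degree(g2)),
                          sort(igraph::degree(graph))))
      if (identical(canonical_edges(g2), orig_edges)) {
        n_stuck <<- n_stuck + 1L
      }
      detect_modules(g2)$q
    }, 0)
    if (n_stuck == n_iter) {
      warning(sprintf("no degree-preserving swap changed the graph in any of %d iteration(s); original modularity recorded",
                      n_iter), call. = FALSE)
    }
    structure(list(samples = samples, mean = mean(samples),
                   sd = stats::sd(samples), n_iter = as.integer(n_iter),
                   seed = seed),
              class = "null_distribution")
  })
}

canonical_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el[order(el[, 1L], el[, 2L], method = "radix"), , drop = FALSE]
}

#' Scaled modularity (null z-score)
#'
#' `(q_obs - null mean) / null sd`: how many null standard deviations the
#' observed modularity lies above the rewiring null.
#'
#' @param q_obs Observed modularity.
#' @param null A `null_distribution` or any list with `mean` and `sd`.
#' @return The scaled modularity score.
#' @export
scaled_modularity <- function(q_obs, null) {
  if (is.null(null$sd) || !is.finite(null$sd) || null$sd <= 0) {
    stopf("null standard deviation must be positive")
  }
  (q_obs - null$mean) / null$sd
}

#' Global connectivity null model over random gene sets
#'
#' Each iteration draws the same number of "altered" genes uniformly at
#' random from the network, rebuilds the subtype network with the same
#' linker cutoff and path threshold, and records the size of its largest
#' connected component (0 for an edgeless result). The observed size, if
#' supplied, gets an empirical upper-tail p-value
#' `(1 + #{null >= observed}) / (n_iter + 1)`.
#'
#' @param net Undirected igraph with named vertices.
#' @param n_altered Number of genes drawn per iteration.
#' @param alpha Linker BH cutoff, as used for the observed network.
#' @param path_threshold See [extract_subnetwork()].
#' @param n_iter Number of iterations (default 1000).
#' @param seed Optional RNG seed.
#' @param observed_size Optional observed largest-component size.
#' @return A `null_distribution` whose `samples` are component sizes, plus
#'   `p_value` when `observed_size` is given.
#' @export
global_null_connectivity <- function(net, n_altered, alpha = 0.05,
                                     path_threshold = 2L, n_iter = 1000L,
                                     seed = NULL, observed_size = NULL) {
  nodes <- igraph::V(net)$name
  check_scalar(n_altered, "n_altered", lower = 1, upper = length(nodes),
               integer = TRUE)
  check_scalar(n_iter, "n_iter", lower = 1, integer = TRUE)
  with_seed(seed, {
    samples <- vapply(seq_len(n_iter), function(i) {
      alt <- sample(nodes, n_altered)
      sn <- suppressMessages(build_subtype_network(net, alt, alpha,
                                                   path_threshold))
      if (igraph::vcount(sn$graph) == 0L) return(0)
      max(igraph::components(sn$graph)$csize)
    }, 0)
    out <- structure(list(samples = samples, mean = mean(samples),
                          sd = stats::sd(samples),
                          n_iter = as.integer(n_iter), seed = seed),
                     class = "null_distribution")
    if (!is.null(observed_size)) {
      out$observed_size <- observed_size
      out$p_value <- (1 + sum(samples >= observed_size)) / (n_iter + 1)
    }
    out
  })
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null distribution: %d samples, mean %.4g, sd %.4g\n",
              x$n_iter, x$mean, x$sd))
  if (!is.null(x$p_value)) {
    cat(sprintf("observed %.4g, empirical upper-tail p = %.4g\n",
                x$observed_size, x$p_value))
  }
  invisible(x)
}
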