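## Shared fixtures and small independent oracles used across test files.

## two triangles joined by one bridge: Q of the triangle partition is 5/14
two_triangle_graph <- function() {
  igraph::make_graph(~ A - B, B - C, C - A, D - E, E - F, F - D, A - D)
}

## two 5-cliques joined by one bridge (planted two-community graph)
two_clique_graph <- function(k = 5L) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k),
                              igraph::make_full_graph(k))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(2L * k))
  igraph::add_edges(g, c("n01", sprintf("n%02d", k + 1L)))
}

## all set partitions of n elements (restricted growth strings); the
## exhaustive oracle for modularity optimisation on tiny graphs
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

## exhaustive maximum modularity over all partitions of the non-isolated
## nodes of g (only feasible for <= 8 nodes)
brute_force_best_q <- function(g) {
  deg <- igraph::degree(g)
  noniso <- names(deg)[deg > 0]
  parts <- all_partitions(length(noniso))
  max(vapply(parts, function(p)
    modularity_q(g, stats::setNames(p, noniso)), 0))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

mean_block_ratio <- function(w, labels) {
  same <- outer(labels, labels, "==") & row(w) != col(w)
  mean(w[same]) / mean(w[outer(labels, labels, "!=")])
}

## simple ARI fallback is deliberately not provided: tests use
## mclust::adjustedRandIndex as the independent implementation
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

rb1_fixture_path <- function() {
  system.file("extdata", "rb1_mirna_targets.tsv", package = "SNFmods",
              mustWork = TRUE)
}
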