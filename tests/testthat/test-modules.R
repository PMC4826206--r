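test_that("subnetwork extraction keeps altered edges and nominates degree-2 linkers", {
  g <- igraph::make_graph(~ A - B, L - A, M - A, M - B, M - C, C - D)
  ex <- suppressMessages(extract_subnetwork(g, c("A", "B", "Z")))
  expect_setequal(ex$altered, c("A", "B"))
  expect_equal(igraph::ecount(ex$altered_graph), 1)  # the A-B edge
  ## L touches one altered gene only; M touches two
  expect_identical(ex$candidates, "M")
  expect_message(extract_subnetwork(g, c("A", "B", "Z")), "dropped 1")
  expect_error(extract_subnetwork(g, character()), "empty")
  expect_error(extract_subnetwork(g, "A", path_threshold = 3), "path_threshold")
})

test_that("candidate linkers equal brute-force common-neighbour enumeration", {
  set.seed(40)
  for (i in 1:20) {
    g <- igraph::sample_gnp(7, 0.45)
    igraph::V(g)$name <- letters[1:7]
    altered <- sample(letters[1:7], 3)
    ex <- suppressMessages(extract_subnetwork(g, altered))
    ## oracle: a non-altered node adjacent to >= 2 altered nodes is exactly
    ## a common neighbour of some altered pair
    expected <- character()
    for (v in setdiff(letters[1:7], altered)) {
      nb <- names(igraph::neighbors(g, v))
      if (sum(nb %in% altered) >= 2) expected <- c(expected, v)
    }
    expect_setequal(ex$candidates, expected)
  }
})

test_that("linker significance equals exact hypergeometric enumeration", {
  ## 10-node graph: candidate L of degree 3 with all 3 neighbours altered,
  ## 4 altered genes among the 9 non-candidate nodes -> tail = C(4,3)/C(9,3)
  g <- igraph::make_graph(~ L - A1, L - A2, L - A3, A4 - B1, B1 - B2,
                          B2 - B3, B3 - B4, B4 - B5)
  altered <- c("A1", "A2", "A3", "A4")
  expect_equal(linker_significance(g, altered, "L"), 4 / 84,
               tolerance = 1e-12)
  ## no altered neighbours: the tail from zero is certain
  expect_equal(linker_significance(g, c("B4", "B5"), "A1"), 1)
  ## monotone in the number of altered neighbours at fixed degree
  p2 <- linker_significance(g, c("A1", "A2", "A4"), "L")
  p3 <- linker_significance(g, altered, "L")
  expect_lt(p3, p2)
  expect_error(linker_significance(g, c("A1", "L"), "L"), "altered")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(41)
  p <- runif(30)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("linker admission respects the BH cutoff at both extremes", {
  g <- igraph::make_graph(~ A - B, M - A, M - B, M - X, X - Y)
  altered <- c("A", "B")
  all_in <- suppressMessages(build_subtype_network(g, altered, alpha = 1))
  expect_identical(all_in$linker_nodes, "M")
  none <- suppressMessages(build_subtype_network(g, altered, alpha = 1e-9))
  expect_length(none$linker_nodes, 0L)
  expect_equal(igraph::ecount(none$graph), 1)  # only A-B survives
})

test_that("a planted hub linker is recovered at the conventional cutoff", {
  ## hub H connects 6 of the 8 altered genes inside a 40-node background
  set.seed(42)
  g <- igraph::sample_gnp(40, 0.06)
  igraph::V(g)$name <- sprintf("g%02d", 1:40)
  altered <- sprintf("g%02d", 1:8)
  hub <- "g40"
  for (a in altered[1:6]) {
    if (!igraph::are_adjacent(g, hub, a)) g <- igraph::add_edges(g, c(hub, a))
  }
  sn <- suppressMessages(build_subtype_network(g, altered, alpha = 0.05))
  expect_true(hub %in% sn$linker_nodes)
})

test_that("modularity matches hand-worked partitions and the igraph implementation", {
  g <- two_triangle_graph()
  part <- c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2)
  expect_equal(modularity_q(g, part), 5 / 14, tolerance = 1e-12)
  one <- c(A = 1, B = 1, C = 1, D = 1, E = 1, F = 1)
  expect_equal(modularity_q(g, one), 0, tolerance = 1e-12)
  ## independent cross-check on random graphs and random partitions
  set.seed(43)
  for (i in 1:15) {
    gr <- igraph::sample_gnp(10, 0.35)
    igraph::V(gr)$name <- letters[1:10]
    if (igraph::ecount(gr) == 0) next
    deg <- igraph::degree(gr)
    noniso <- names(deg)[deg > 0]
    mem <- stats::setNames(sample(1:3, length(noniso), TRUE), noniso)
    expect_equal(modularity_q(gr, mem),
                 igraph::modularity(igraph::induced_subgraph(gr, noniso),
                                    mem[noniso]),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(igraph::make_empty_graph(3, directed = FALSE),
                            c(a = 1)), "empty edge set")
})

test_that("module detection recovers separated cliques and the triangle pair", {
  gk <- igraph::disjoint_union(igraph::make_full_graph(4),
                               igraph::make_full_graph(4))
  igraph::V(gk)$name <- letters[1:8]
  dm <- detect_modules(gk)
  expect_length(dm$modules, 2L)
  expect_setequal(dm$modules[[1]], letters[1:4])
  expect_setequal(dm$modules[[2]], letters[5:8])

  dt <- detect_modules(two_triangle_graph())
  expect_equal(dt$q, 5 / 14, tolerance = 1e-12)
  expect_setequal(dt$modules[[1]], c("A", "B", "C"))

  expect_error(detect_modules(igraph::make_empty_graph(2,
                                                       directed = FALSE)),
               "edgeless")
})

test_that("detected partitions cover exactly the non-isolated nodes with Q >= 0", {
  set.seed(44)
  for (i in 1:15) {
    g <- igraph::sample_gnp(12, 0.2)
    igraph::V(g)$name <- sprintf("v%02d", 1:12)
    if (igraph::ecount(g) == 0) next
    dm <- detect_modules(g)
    deg <- igraph::degree(g)
    expect_setequal(names(dm$membership), names(deg)[deg > 0])
    expect_setequal(unlist(dm$modules), names(deg)[deg > 0])
    expect_gte(dm$q, 0)
    expect_lte(dm$q, 1)
  }
})

test_that("detected modularity reaches the exhaustive optimum on tiny graphs", {
  set.seed(45)
  ok <- 0
  n_run <- 40
  for (i in seq_len(n_run)) {
    n <- sample(4:7, 1)
    repeat {
      g <- igraph::sample_gnp(n, 0.5)
      if (igraph::ecount(g) > 0) break
    }
    igraph::V(g)$name <- letters[seq_len(n)]
    if (detect_modules(g)$q >= brute_force_best_q(g) - 1e-9) ok <- ok + 1
  }
  expect_gte(ok / n_run, 0.95)
})

test_that("rewiring preserves the degree multiset and seeds reproduce", {
  g <- two_clique_graph()
  null1 <- local_null_modularity(g, n_iter = 60, seed = 9)
  null2 <- local_null_modularity(g, n_iter = 60, seed = 9)
  expect_identical(null1$samples, null2$samples)
  expect_length(null1$samples, 60L)
  ## degree preservation, checked directly on fresh rewires
  degs <- sort(igraph::degree(g))
  set.seed(10)
  for (i in 1:25) {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
    expect_identical(sort(igraph::degree(g2)), degs)
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
  }
})

test_that("a planted two-clique graph is far more modular than its rewired null", {
  g <- two_clique_graph()
  obs <- detect_modules(g)$q
  null <- local_null_modularity(g, n_iter = 200, seed = 11)
  expect_gt(obs, null$mean + 3 * null$sd)
  expect_gt(scaled_modularity(obs, null), 3)
})

test_that("scaled modularity is a plain null z-score", {
  expect_equal(scaled_modularity(0.326, list(mean = 0.018, sd = 0.01)),
               30.8, tolerance = 1e-10)
  expect_equal(scaled_modularity(0.5, list(mean = 0.5, sd = 0.2)), 0)
  expect_equal(scaled_modularity(1.018, list(mean = 0.018, sd = 0.01)),
               100)
  expect_error(scaled_modularity(0.3, list(mean = 0.1, sd = 0)),
               "positive")
})

test_that("the global connectivity null behaves at its boundary and sizes correctly", {
  g <- two_clique_graph()
  null_all <- global_null_connectivity(g, igraph::vcount(g), alpha = 0.05,
                                       n_iter = 10, seed = 12)
  ## drawing every node reproduces the full network's largest component
  expect_true(all(null_all$samples ==
                    max(igraph::components(g)$csize)))
  null <- global_null_connectivity(g, 4, alpha = 0.05, n_iter = 50,
                                   seed = 13, observed_size = 10)
  expect_length(null$samples, 50L)
  expect_true(null$p_value > 0 && null$p_value <= 1)
})
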