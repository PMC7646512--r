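two_node_net <- function(w = 1) {
  ksp_network_from_edges(
    data.frame(from = "K1", to = "P1", weight = w), kinases = "K1")
}

test_that("integrated network: union, largest component, kinase flags", {
  pairs <- toy_pairs(list(K1 = c("AAAAAAASAAAAAAA")))
  pairs$substrate_id <- "P1"
  ppi <- data.table::data.table(protein_a = c("P1", "P3"),
                                protein_b = c("P2", "P4"))
  net <- build_integrated_network(pairs, ppi)
  expect_setequal(igraph::V(net$graph)$name, c("K1", "P1", "P2"))
  expect_identical(net$kinases, "K1")

  # a kinase that is also a substrate stays a single kinase-flagged node
  p2 <- data.table::data.table(
    kinase_id = c("K1", "K2"), substrate_id = c("P1", "K1"),
    position = c(10L, 20L), residue = "S",
    peptide = "AAAAAAASAAAAAAA")
  net2 <- build_integrated_network(p2)
  expect_setequal(net2$kinases, c("K1", "K2"))
  expect_equal(igraph::vcount(net2$graph), 3)
})

test_that("kinase-substrate edge weight counts distinct sites", {
  pairs <- data.table::data.table(
    kinase_id = "K1", substrate_id = "P1", position = c(3L, 9L, 27L),
    residue = "S", peptide = "AAAAAAASAAAAAAA")
  net <- build_integrated_network(pairs)
  expect_identical(unname(ks_terms(net, "K1", "P1")["KS0"]), 3)
  # PPI support on the same pair does not override the larger site count
  ppi <- data.table::data.table(protein_a = "K1", protein_b = "P1")
  net2 <- build_integrated_network(pairs, ppi)
  expect_identical(unname(ks_terms(net2, "K1", "P1")["KS0"]), 3)
})

test_that("punitive factor follows the log-degree formula", {
  # star-ish graph with degrees 2, 4, 8 on selected nodes
  edges <- rbind(
    data.frame(from = "H", to = paste0("L", 1:8)),         # degree 8 hub
    data.frame(from = "M", to = c("L1", "L2", "L3", "L4")),# degree 4
    data.frame(from = "D", to = c("L5", "L6")))            # degree 2
  net <- ksp_network_from_edges(edges, "H")
  expect_identical(punitive_factor(net, "D"), 1)
  expect_identical(punitive_factor(net, "L7"), 1)
  expect_equal(punitive_factor(net, "H"), 0.8)
  # degrees {1, 2, 4, 8}: min log2 = 0, max = 3 -> p(M) = 1 - 0.2 * 2/3
  expect_equal(punitive_factor(net, "M"), 1 - 0.2 * 2 / 3)
  expect_error(punitive_factor(net, "NOPE"), "unknown node")
})

test_that("punitive factor of a degenerate uniform-degree network is 1", {
  # triangle of triangles is overkill; a 4-cycle with chords: all degree 3
  edges <- data.frame(from = c("A", "B", "C", "D", "A", "B"),
                      to   = c("B", "C", "D", "A", "C", "D"))
  net <- ksp_network_from_edges(edges, "A")
  expect_identical(punitive_factor(net, "A"), 1)
})

test_that("ks_terms on hand-built paths matches the worked examples", {
  expect_equal(unname(ks_terms(two_node_net(3), "K1", "P1")),
               c(3, 0, 0, 0))
  # path k-a-b-n with weights 2, 3, 5 -> only a length-3 simple path
  net <- ksp_network_from_edges(
    data.frame(from = c("K", "A", "B"), to = c("A", "B", "N"),
               weight = c(2, 3, 5)), "K")
  expect_equal(unname(ks_terms(net, "K", "N")), c(0, 0, 30, 0))
  # path k-a-c-b-n, unit weights -> single length-4 simple path
  net2 <- ksp_network_from_edges(
    data.frame(from = c("K", "A", "C", "B"), to = c("A", "C", "B", "N")),
    "K")
  expect_equal(unname(ks_terms(net2, "K", "N")), c(0, 0, 0, 1))
  expect_error(ks_terms(net2, "K", "K"), "distinct")
})

test_that("simple and literal modes match their brute-force oracles", {
  set.seed(101)
  for (i in 1:60) {
    net <- random_connected_net(sample(4:10, 1))
    nm <- igraph::V(net$graph)$name
    pick <- sample(nm, 2)
    expect_equal(unname(ks_terms(net, pick[1], pick[2], "simple")),
                 oracle_ks_simple(net, pick[1], pick[2]), tolerance = 1e-12)
    expect_equal(unname(ks_terms(net, pick[1], pick[2], "literal")),
                 oracle_ks_literal(net, pick[1], pick[2]), tolerance = 1e-12)
  }
})

test_that("KS terms are homogeneous of degree length+1 in the weights", {
  set.seed(5)
  net <- random_connected_net(8)
  el <- igraph::as_data_frame(net$graph, what = "edges")
  el$weight <- el$weight * 2
  net2 <- ksp_network_from_edges(el, net$kinases)
  nm <- igraph::V(net$graph)$name
  t1 <- ks_terms(net, nm[1], nm[5])
  t2 <- ks_terms(net2, nm[1], nm[5])
  expect_equal(unname(t2), unname(t1 * 2^(1:4)), tolerance = 1e-12)
})

test_that("simple-mode KS terms are symmetric in the endpoints", {
  set.seed(6)
  for (i in 1:10) {
    net <- random_connected_net(8)
    nm <- igraph::V(net$graph)$name
    pick <- sample(nm, 2)
    expect_equal(unname(ks_terms(net, pick[1], pick[2], "simple")),
                 unname(ks_terms(net, pick[2], pick[1], "simple")))
  }
})

test_that("ksp_score applies beta and the kinase punitive factor", {
  expect_equal(ksp_score(two_node_net(1), "K1", "P1"), 0.25)
  # all terms zero -> 0
  net <- ksp_network_from_edges(
    data.frame(from = c("K", "A", "B", "C", "D"),
               to = c("A", "B", "C", "D", "N")), "K")
  expect_identical(ksp_score(net, "K", "N"), 0)
  # random graph: equals beta-weighted oracle terms times p_d(k)
  set.seed(9)
  for (i in 1:10) {
    rnet <- random_connected_net(9)
    nm <- igraph::V(rnet$graph)$name
    beta <- c(0.25, 0.225, 0.1875, 0.1875)
    expect_equal(
      ksp_score(rnet, nm[1], nm[4], beta),
      sum(beta * oracle_ks_simple(rnet, nm[1], nm[4])) *
        punitive_factor(rnet, nm[1]),
      tolerance = 1e-12)
  }
  expect_error(ksp_score(two_node_net(), "K1", "P1", beta = c(1, 2)),
               "beta")
})

test_that("affinity graph stores exactly the nonzero kinase-protein scores", {
  aff <- build_affinity_graph(two_node_net(1))
  expect_identical(nrow(aff$edges), 1L)
  expect_equal(aff$edges$score, 0.25)

  # kinase more than 4 hops from a protein gets no edge
  edges <- data.frame(from = c("K", "A", "B", "C", "D"),
                      to = c("A", "B", "C", "D", "N"))
  aff2 <- build_affinity_graph(ksp_network_from_edges(edges, "K"))
  expect_false("N" %in% aff2$edges$protein_id)

  # every stored edge agrees with the per-pair score; bound |E2| <= |K||N|
  set.seed(12)
  net <- random_connected_net(10)
  aff3 <- build_affinity_graph(net)
  expect_lte(nrow(aff3$edges),
             length(aff3$kinases) * length(aff3$proteins))
  for (r in sample(nrow(aff3$edges), min(5, nrow(aff3$edges)))) {
    e <- aff3$edges[r]
    expect_equal(e$score, ksp_score(net, e$kinase_id, e$protein_id),
                 tolerance = 1e-12)
  }
})

test_that("literal-mode affinity graph matches per-pair literal scores", {
  set.seed(13)
  net <- random_connected_net(8)
  aff <- build_affinity_graph(net, mode = "literal")
  for (r in seq_len(nrow(aff$edges))) {
    e <- aff$edges[r]
    expect_equal(e$score,
                 ksp_score(net, e$kinase_id, e$protein_id, mode = "literal"),
                 tolerance = 1e-12)
  }
})

test_that("network ranking sorts, breaks ties lexicographically, flags misses", {
  aff <- structure(list(
    edges = data.table::data.table(
      kinase_id = c("K2", "K1", "K3"), protein_id = "P1",
      score = c(0.2, 0.5, 0.2)),
    kinases = c("K1", "K2", "K3"), proteins = "P1",
    beta = ksp_default_beta(), mode = "simple"), class = "ksp_affinity")
  site <- list(substrate_id = "P1")
  rk <- rank_kinases_network(aff, site, top_k = 10)
  expect_identical(rk$kinase_id, c("K1", "K2", "K3"))  # tie K2/K3 lexical
  expect_false(attr(rk, "substrate_missing"))
  expect_identical(nrow(rank_kinases_network(aff, site, top_k = 2)), 2L)
  miss <- rank_kinases_network(aff, list(substrate_id = "NOPE"), 10)
  expect_identical(nrow(miss), 0L)
  expect_true(attr(miss, "substrate_missing"))
})
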