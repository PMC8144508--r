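test_that("complete graph topology is the closed-form limit", {
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- letters[1:5]
  igraph::E(g)$weight <- 1
  ts <- topologySummary(g, swReplicates = 10, seed = 1)
  expect_equal(ts$density, 1)
  expect_equal(ts$connectedness, 1)
  expect_equal(ts$clustering_coefficient, 1)
  expect_equal(ts$characteristic_path_length, 1)
  expect_equal(ts$diameter, 1)
  expect_equal(ts$efficiency, 1)
})

test_that("twin triangles with the component partition have modularity 1/2", {
  edges <- data.frame(from = c("a", "b", "c", "d", "e", "f"),
                      to = c("b", "c", "a", "e", "f", "d"))
  g <- edgeGraph(edges)
  part <- manualPartition(
    setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "d", "e", "f")),
    g)
  # brute-force Newman formula with m = 6: 2 * (3/6 - (6/12)^2) = 0.5
  expect_equal(part@modularity, 0.5)
  ts <- topologySummary(g, partition = part, swReplicates = 10, seed = 1)
  expect_equal(ts$modularity, 0.5)
  expect_equal(ts$connectedness, (3 + 3) / 15)  # 2 triangles of 6 nodes
})

test_that("a star is maximally centralized and hub-dominated", {
  g <- igraph::make_star(6, mode = "undirected")
  igraph::V(g)$name <- c("hub", paste0("leaf", 1:5))
  igraph::E(g)$weight <- 1
  ts <- topologySummary(g, swReplicates = 10, seed = 1)
  expect_equal(ts$freeman_betweenness_centralization, 1)
  cent <- nodeCentralities(g)
  expect_equal(cent$betweenness[cent$node == "hub"], choose(5, 2))
  expect_true(all(cent$betweenness[cent$node != "hub"] == 0))
})

test_that("path betweenness puts all intermediation on the middle node", {
  g <- edgeGraph(data.frame(from = c("a", "b"), to = c("b", "c")))
  cent <- nodeCentralities(g)
  expect_equal(cent$betweenness[match(c("a", "b", "c"), cent$node)],
               c(0, 1, 0))
})

test_that("symmetric rings have uniform centralities", {
  g <- igraph::make_ring(6)
  igraph::V(g)$name <- letters[1:6]
  igraph::E(g)$weight <- 0.4
  cent <- nodeCentralities(g)
  expect_equal(cent$eigencentrality, rep(1, 6))
  expect_equal(diff(range(cent$betweenness)), 0)
  expect_equal(cent$strength, rep(0.8, 6))
})

test_that("eigencentrality matches a dense eigen-solver oracle", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    W <- matrix(0, n, n)
    upper <- which(upper.tri(W))
    picked <- sample(upper, size = max(n, length(upper) %/% 2))
    W[picked] <- runif(length(picked), 0.1, 1)
    W <- W + t(W)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    keep <- igraph::components(g)$membership ==
      which.max(igraph::components(g)$csize)
    g <- igraph::induced_subgraph(g, which(keep))
    A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    ev <- eigen(A, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / max(abs(ev))
    cent <- nodeCentralities(g)
    expect_equal(cent$eigencentrality, unname(ev), tolerance = 1e-8)
  }
})

test_that("assortativity separates homophilous from hub-and-spoke patterns", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:6)
  igraph::E(star)$weight <- 1
  vals <- setNames(c(10, 1, 1, 1, 1, 1), paste0("n", 1:6))
  expect_lt(centralityAssortativity(star, vals), 0)

  cliqueA <- t(combn(paste0("a", 1:4), 2))
  cliqueB <- t(combn(paste0("b", 1:4), 2))
  g <- edgeGraph(data.frame(
    from = c(cliqueA[, 1], cliqueB[, 1], "a1"),
    to = c(cliqueA[, 2], cliqueB[, 2], "b1")))
  v2 <- setNames(c(rep(1, 4), rep(5, 4)), c(paste0("a", 1:4), paste0("b", 1:4)))
  # direct Pearson over the doubled edge list as oracle
  el <- igraph::as_edgelist(g)
  x <- c(v2[el[, 1]], v2[el[, 2]])
  y <- c(v2[el[, 2]], v2[el[, 1]])
  expect_equal(centralityAssortativity(g, v2), cor(x, y))
  expect_gt(centralityAssortativity(g, v2), 0.8)
  expect_error(centralityAssortativity(g, v2 * 0 + 1), "constant")
})

test_that("assortativity of random values on a random graph is centred at 0", {
  # note the finite-size bias of order -1/(n-1); large n keeps it small
  set.seed(61)
  vals <- replicate(200, {
    g <- igraph::sample_gnp(100, 0.08)
    igraph::V(g)$name <- paste0("v", 1:100)
    igraph::E(g)$weight <- 1
    v <- setNames(rnorm(100), paste0("v", 1:100))
    centralityAssortativity(g, v)
  })
  expect_lt(abs(mean(vals)), 0.03)
})

test_that("hierarchy layers are BFS depths on the strongest-edge forest", {
  # tree rooted at the hub: layers are plain BFS depth
  tree <- edgeGraph(data.frame(from = c("r", "r", "x", "x"),
                               to = c("x", "y", "u", "v"),
                               weight = c(0.9, 0.8, 0.7, 0.6)))
  h <- hierarchyLayers(tree)
  # x carries the most incident weight, so it is the eigencentral root;
  # layers are BFS depths from it
  expect_equal(h$root, "x")
  expect_equal(h$layers[[h$root]], 0L)
  expect_equal(h$layers[c("r", "u", "v", "y")],
               setNames(c(1L, 1L, 1L, 2L), c("r", "u", "v", "y")))
  expect_length(h$unreachable, 0)

  # triangle: the weakest edge (0.1) is the one broken
  tri <- edgeGraph(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                              weight = c(0.9, 0.8, 0.1)))
  h2 <- hierarchyLayers(tri)
  expect_equal(h2$root, "b")  # carries the 0.9 and 0.8 edges
  expect_equal(h2$layers[["a"]], 1L)
  expect_equal(h2$layers[["c"]], 1L)  # via b, not via the dropped 0.1 edge

  # isolated node: flagged unreachable, no layer
  iso <- edgeGraph(data.frame(from = "a", to = "b", weight = 1),
                   nodes = data.frame(name = c("a", "b", "M5")))
  h3 <- hierarchyLayers(iso)
  expect_equal(h3$unreachable, "M5")
  expect_true(is.na(h3$layers[["M5"]]))
})

test_that("degree-distribution comparison matches a CDF-scan oracle", {
  g1 <- igraph::sample_gnp(40, 0.1)
  g2 <- igraph::sample_gnp(40, 0.3)
  igraph::V(g1)$name <- paste0("a", 1:40)
  igraph::V(g2)$name <- paste0("b", 1:40)
  igraph::E(g1)$weight <- 1
  igraph::E(g2)$weight <- 1
  res <- compareDegreeDistributions(g1, g2)
  d1 <- igraph::degree(g1)
  d2 <- igraph::degree(g2)
  grid <- sort(unique(c(d1, d2)))
  sup <- max(abs(vapply(grid, function(t) mean(d1 <= t) - mean(d2 <= t),
                        numeric(1))))
  expect_equal(res$D, sup, tolerance = 1e-12)
  # identical networks -> D = 0, p = 1
  same <- compareDegreeDistributions(g1, g1)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  # complete vs empty graph -> D = 1
  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- paste0("f", 1:5)
  igraph::E(full)$weight <- 1
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  empty <- igraph::set_vertex_attr(empty, "name", value = paste0("e", 1:5))
  expect_equal(compareDegreeDistributions(full, empty)$D, 1)
})

test_that("density and connectedness never decrease when an edge is added", {
  set.seed(71)
  for (i in 1:10) {
    g <- igraph::sample_gnp(12, 0.15)
    igraph::V(g)$name <- paste0("v", 1:12)
    igraph::E(g)$weight <- 1
    miss <- which(!igraph::as_adjacency_matrix(g, sparse = FALSE) &
                    upper.tri(matrix(0, 12, 12)), arr.ind = TRUE)
    if (nrow(miss) == 0) next
    pick <- miss[sample(nrow(miss), 1), ]
    g2 <- igraph::add_edges(g, c(pick[1], pick[2]), attr = list(weight = 1))
    expect_gte(igraph::edge_density(g2), igraph::edge_density(g))
    c1 <- topologySummary(g, swReplicates = 2, seed = 1)$connectedness
    c2 <- topologySummary(g2, swReplicates = 2, seed = 1)$connectedness
    expect_gte(c2, c1)
  }
})

test_that("efficiency is bounded below by the inverse diameter", {
  set.seed(73)
  for (i in 1:10) {
    g <- igraph::sample_gnm(15, 25)
    if (igraph::components(g)$no > 1) next
    igraph::V(g)$name <- paste0("v", 1:15)
    igraph::E(g)$weight <- 1
    ts <- topologySummary(g, swReplicates = 2, seed = 1)
    expect_gte(ts$efficiency + 1e-12, 1 / ts$diameter)
  }
})

test_that("the small-world index of an Erdos-Renyi graph is about 1", {
  set.seed(79)
  vals <- replicate(8, {
    g <- igraph::sample_gnm(40, 120)
    igraph::V(g)$name <- paste0("v", 1:40)
    igraph::E(g)$weight <- 1
    topologySummary(g, swReplicates = 50, seed = sample(1e4, 1))$small_world_index
  })
  expect_equal(mean(vals), 1, tolerance = 0.15)
})
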