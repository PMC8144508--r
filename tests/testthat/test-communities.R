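twoCliques <- function() {
  a <- t(combn(paste0("a", 1:4), 2))
  b <- t(combn(paste0("b", 1:4), 2))
  edgeGraph(data.frame(from = c(a[, 1], b[, 1], "a1"),
                       to = c(a[, 2], b[, 2], "b1")))
}

test_that("Louvain separates two cliques and merges a complete graph", {
  p <- louvainPartition(twoCliques(), seed = 1)
  memb <- partitionMembership(p)
  expect_equal(max(memb), 2L)
  expect_length(unique(memb[paste0("a", 1:4)]), 1L)
  expect_length(unique(memb[paste0("b", 1:4)]), 1L)
  expect_gt(p@modularity, 0.3)

  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("v", 1:6)
  igraph::E(k6)$weight <- 1
  expect_equal(max(partitionMembership(louvainPartition(k6, seed = 1))), 1L)
})

test_that("Louvain is at least as good as the singleton partition", {
  set.seed(83)
  for (i in 1:5) {
    g <- igraph::sample_gnm(20, 40)
    igraph::V(g)$name <- paste0("v", 1:20)
    igraph::E(g)$weight <- runif(40)
    p <- louvainPartition(g, seed = i)
    singleton <- igraph::modularity(g, seq_len(20), weights = igraph::E(g)$weight)
    expect_gte(p@modularity, singleton)
  }
})

test_that("an edgeless graph yields the singleton partition", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = letters[1:4])
  p <- louvainPartition(g, seed = 1)
  expect_equal(unname(partitionMembership(p)), 1:4)
  expect_equal(p@modularity, 0)
})

test_that("Spinglass handles disconnected graphs per component, with a seed", {
  a <- t(combn(paste0("a", 1:4), 2))
  b <- t(combn(paste0("b", 1:4), 2))
  g <- edgeGraph(data.frame(from = c(a[, 1], b[, 1]),
                            to = c(a[, 2], b[, 2])))
  p <- spinglassPartition(g, seed = 2)
  memb <- partitionMembership(p)
  expect_length(unique(memb[paste0("a", 1:4)]), 1L)
  expect_length(unique(memb[paste0("b", 1:4)]), 1L)
  expect_equal(max(memb), 2L)
  # determinism contract
  p2 <- spinglassPartition(g, seed = 2)
  expect_identical(partitionMembership(p), partitionMembership(p2))
})

test_that("planted blocks are recovered by both algorithms", {
  spec <- plantedBlockSpec(nPerBlock = 6, nBlocks = 4, n = 200,
                           within = 0.6, between = 0.1, seed = 43)
  co <- generateCohort(spec)
  net <- cohortNetwork(co)
  truth <- setNames(as.integer(factor(attr(co, "blocks"))),
                    names(attr(co, "blocks")))
  lou <- louvainPartition(net, seed = 1)
  expect_gt(partitionDistance(lou, truth)$normalized_mutual_information, 0.9)
  spin <- spinglassPartition(net, seed = 1)
  expect_gt(partitionDistance(spin, truth)$normalized_mutual_information, 0.8)
})

test_that("partition distances hit their closed forms", {
  ids <- letters[1:4]
  same <- setNames(c(1, 1, 2, 2), ids)
  d0 <- partitionDistance(same, same)
  expect_equal(d0$variation_of_information, 0)
  expect_equal(d0$normalized_mutual_information, 1)
  expect_equal(d0$rand_index, 1)

  singletons <- setNames(1:4, ids)
  oneBlock <- setNames(rep(1, 4), ids)
  d1 <- partitionDistance(singletons, oneBlock)
  expect_equal(d1$variation_of_information, 2)  # H = log2(4) bits
  expect_equal(d1$rand_index, 0)
  expect_equal(d1$normalized_mutual_information, 0)
  expect_error(partitionDistance(same, setNames(1:3, letters[2:4])),
               "different nodes")
})

test_that("partition metrics match the igraph contingency oracle", {
  set.seed(89)
  for (i in 1:10) {
    n <- 100
    a <- setNames(sample(1:5, n, replace = TRUE), paste0("v", 1:n))
    b <- setNames(sample(1:4, n, replace = TRUE), paste0("v", 1:n))
    d <- partitionDistance(a, b)
    expect_equal(d$variation_of_information,
                 igraph::compare(a, b, method = "vi") / log(2),
                 tolerance = 1e-10)
    expect_equal(d$normalized_mutual_information,
                 igraph::compare(a, b, method = "nmi"), tolerance = 1e-10)
    expect_equal(d$rand_index,
                 igraph::compare(a, b, method = "rand"), tolerance = 1e-10)
  }
})

test_that("variation of information satisfies the triangle inequality", {
  set.seed(97)
  vi <- function(p, q) partitionDistance(p, q)$variation_of_information
  for (i in 1:10) {
    n <- 30
    ids <- paste0("v", 1:n)
    p <- setNames(sample(1:4, n, TRUE), ids)
    q <- setNames(sample(1:4, n, TRUE), ids)
    r <- setNames(sample(1:4, n, TRUE), ids)
    expect_lte(vi(p, r), vi(p, q) + vi(q, r) + 1e-10)
  }
})

test_that("cluster contraction aggregates inter-cluster weight exactly", {
  g <- edgeGraph(data.frame(
    from = c("a1", "a1", "a2", "b1", "a1", "a2", "a3"),
    to = c("a2", "a3", "a3", "b2", "b1", "b1", "b2"),
    weight = c(0.9, 0.8, 0.7, 0.95, 0.1, 0.2, 0.3)))
  part <- manualPartition(
    setNames(c(1, 1, 1, 2, 2), c("a1", "a2", "a3", "b1", "b2")), g)
  res <- contractClusters(g, part)
  expect_equal(igraph::vcount(res$graph), 2L)
  expect_equal(igraph::ecount(res$graph), 1L)
  expect_equal(igraph::E(res$graph)$weight, 0.1 + 0.2 + 0.3)
  # representative is the member with the greatest eigencentrality
  cent <- nodeCentralities(g)
  for (k in 1:2) {
    members <- names(partitionMembership(part))[partitionMembership(part) == k]
    best <- members[which.max(cent$eigencentrality[match(members, cent$node)])]
    expect_equal(unname(res$representatives[as.character(k)]), best)
  }
  # singleton partition -> identity network
  singles <- manualPartition(
    setNames(1:5, c("a1", "a2", "a3", "b1", "b2")), g)
  idn <- contractClusters(g, singles)
  expect_equal(igraph::vcount(idn$graph), 5L)
  expect_equal(igraph::ecount(idn$graph), igraph::ecount(g))
  expect_equal(sum(igraph::E(idn$graph)$weight), sum(igraph::E(g)$weight))
})

test_that("angular eigenvector ordering groups correlated variables", {
  set.seed(101)
  z <- rnorm(80)
  w <- rnorm(80)
  vals <- cbind(x1 = z + rnorm(80, sd = 0.3), x2 = z + rnorm(80, sd = 0.3),
                y1 = w + rnorm(80, sd = 0.3), y2 = w + rnorm(80, sd = 0.3))
  ord <- angularOrder(spearmanMatrix(vals))
  posx <- range(match(c("x1", "x2"), ord))
  posy <- range(match(c("y1", "y2"), ord))
  # members of the same correlated pair sit adjacently
  expect_equal(diff(posx), 1)
  expect_equal(diff(posy), 1)
})
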