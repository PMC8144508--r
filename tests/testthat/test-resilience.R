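test_that("connectivity loss counts reachable pairs", {
  path <- edgeGraph(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(connectivityLoss(path, character(0)), 0)
  expect_equal(connectivityLoss(path, c("a", "b", "c")), 1)
  expect_equal(connectivityLoss(path, "b"), 1)    # endpoints disconnect fully
  expect_equal(connectivityLoss(path, "a"), 1 - 1 / 3)
  expect_error(connectivityLoss(path, "zz"))
})

test_that("connectivity loss matches the reachability oracle on small graphs", {
  set.seed(103)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    adj <- matrix(FALSE, n, n)
    upper <- which(upper.tri(adj))
    on <- sample(upper, sample(2:length(upper), 1))
    adj[on] <- TRUE
    adj <- adj | t(adj)
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::E(g)$weight <- 1
    base <- connectedPairsOracle(adj)
    if (base == 0) next
    removed <- sample(rownames(adj), sample(0:(n - 1), 1))
    keep <- setdiff(rownames(adj), removed)
    oracle <- 1 - connectedPairsOracle(adj[keep, keep, drop = FALSE]) / base
    expect_equal(connectivityLoss(g, removed), oracle)
  }
})

test_that("attack strategies order removals as specified", {
  star <- igraph::make_star(8, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("l", 1:7))
  igraph::E(star)$weight <- 1
  deg <- attackNetwork(star, "degree")
  expect_equal(deg$removal_order[1], "hub")
  expect_equal(deg$loss[1], 1)      # hub removal disconnects everything

  casc <- attackNetwork(star, "cascading")
  expect_equal(casc$removal_order[1], "hub")

  # clique: loss after k removals is purely combinatorial
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("v", 1:5)
  igraph::E(k5)$weight <- 1
  for (strat in c("degree", "betweenness", "cascading")) {
    cu <- attackNetwork(k5, strat)
    expected <- 1 - choose(5 - seq_len(5), 2) / choose(5, 2)
    expect_equal(cu$loss, expected)
  }
})

test_that("attack curves are monotone and end at total loss", {
  set.seed(107)
  g <- igraph::sample_gnm(15, 25)
  igraph::V(g)$name <- paste0("v", 1:15)
  igraph::E(g)$weight <- runif(25)
  for (strat in c("degree", "betweenness", "cascading")) {
    cu <- attackNetwork(g, strat)
    expect_true(all(diff(cu$loss) >= -1e-12))
    expect_equal(cu$loss[length(cu$loss)], 1)
  }
  r1 <- attackNetwork(g, "random", seed = 5, nRandomReps = 10)
  r2 <- attackNetwork(g, "random", seed = 5, nRandomReps = 10)
  expect_identical(r1$loss, r2$loss)   # determinism contract
  expect_true(all(diff(r1$loss) >= -1e-12))
})

test_that("directed attacks dominate random ones on scale-free graphs", {
  set.seed(109)
  dominance <- replicate(5, {
    g <- igraph::sample_pa(40, m = 2, directed = FALSE)
    igraph::V(g)$name <- paste0("v", 1:40)
    igraph::E(g)$weight <- 1
    rnd <- attackNetwork(g, "random", seed = 11, nRandomReps = 20)$loss
    deg <- attackNetwork(g, "degree")$loss
    casc <- attackNetwork(g, "cascading")$loss
    c(mean(deg - rnd), mean(casc - rnd))
  })
  expect_true(all(colMeans(t(dominance)) > 0))
})

test_that("cascading attacks remove cut vertices before leaves", {
  # caterpillar tree: internal spine nodes are cut vertices
  tree <- edgeGraph(data.frame(
    from = c("s1", "s2", "s1", "s1", "s2", "s2"),
    to = c("s2", "s3", "l1", "l2", "l3", "l4")))
  cu <- attackNetwork(tree, "cascading")
  nLeaves <- 5  # l1..l4 and s3
  firstLeaf <- min(match(c("l1", "l2", "l3", "l4", "s3"), cu$removal_order))
  spine <- match(c("s1", "s2"), cu$removal_order)
  expect_true(all(spine < firstLeaf))
})

test_that("removal fraction interpolates the loss curve from below", {
  cu <- list(loss = (1:10 / 10)^2, n = 10)
  expect_equal(removalFractionForLoss(cu, 0.7), 9 / 10)  # (9/10)^2 >= 0.7
  expect_equal(removalFractionForLoss(cu, 1), 1)
  one <- list(loss = c(1, 1), n = 2)
  expect_equal(removalFractionForLoss(one, 0.5), 1 / 2)
  expect_error(removalFractionForLoss(cu, 0), "targetLoss")
})

test_that("differential networks partition the union of edge sets", {
  gA <- edgeGraph(data.frame(from = c("a", "b"), to = c("b", "c")))
  gB <- edgeGraph(data.frame(from = c("b", "c"), to = c("c", "d")))
  d <- differentialNetwork(gA, gB)
  expect_equal(unname(d$counts),
               c(1L, 1L, 1L, 3L), ignore_attr = TRUE)
  expect_equal(d$edges$origin[d$edges$var_a == "b" & d$edges$var_b == "c"],
               "shared")
  expect_equal(d$edges$origin[d$edges$var_a == "a"], "a_only")
  expect_equal(d$edges$origin[d$edges$var_a == "c"], "b_only")
  # bookkeeping identities
  expect_equal(d$counts[["shared"]] + d$counts[["a_only"]],
               igraph::ecount(gA))
  expect_equal(d$counts[["shared"]] + d$counts[["b_only"]],
               igraph::ecount(gB))
  # identical networks: everything shared
  dSame <- differentialNetwork(gA, gA)
  expect_equal(dSame$counts[["shared"]], igraph::ecount(gA))
  expect_equal(dSame$counts[["a_only"]] + dSame$counts[["b_only"]], 0L)
  # disjoint edge sets: nothing shared
  gC <- edgeGraph(data.frame(from = "x", to = "y"))
  expect_equal(differentialNetwork(gA, gC)$counts[["shared"]], 0L)
})
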