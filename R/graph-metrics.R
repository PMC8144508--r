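# Topology battery, node centralities, assortativity of centralities,
# hierarchy layering, and degree-distribution comparison.

asPhysioNetwork <- function(g, pThreshold = NA_real_) {
  if (is(g, "PhysioNetwork")) return(g)
  if (igraph::is_igraph(g)) {
    if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    return(new("PhysioNetwork", graph = g, pThreshold = pThreshold))
  }
  stop("expected a PhysioNetwork or igraph object")
}

# Krackhardt connectedness: fraction of unordered node pairs joined by a path.
krackhardtConnectedness <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(NA_real_)
  sizes <- igraph::components(g)$csize
  sum(sizes * (sizes - 1) / 2) / (n * (n - 1) / 2)
}

# Mean local weighted clustering coefficient (Onnela/Fagiolo): per node,
# geometric-mean triangle intensity with weights rescaled by the maximum
# weight; nodes of degree < 2 contribute 0. On an unweighted graph this is
# the usual mean local clustering.
weightedClustering <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(NA_real_)
  if (igraph::ecount(g) == 0) return(0)
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  Wn <- (W / max(W))^(1 / 3)
  deg <- rowSums(W > 0)
  tri <- diag(Wn %*% Wn %*% Wn)
  ci <- ifelse(deg >= 2, tri / (deg * (deg - 1)), 0)
  mean(ci)
}

# Global efficiency on the unweighted graph: mean over distinct ordered pairs
# of 1/d(i,j), unreachable pairs contributing 0.
globalEfficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(NA_real_)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

# Unweighted characteristic path length and diameter on the largest component.
largestComponentPaths <- function(g) {
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  if (igraph::vcount(sub) < 2) return(list(cpl = NA_real_, diameter = NA_real_))
  list(cpl = igraph::mean_distance(sub, weights = NA, directed = FALSE),
       diameter = igraph::diameter(sub, weights = NA, directed = FALSE))
}

# Freeman betweenness centralization with the standard normalization.
freemanBetweennessCentralization <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) return(NA_real_)
  igraph::centr_betw(g, directed = FALSE)$centralization
}

# Small-world index (C/C_rand)/(L/L_rand) against an Erdos-Renyi G(n, m)
# ensemble matched on node and edge counts. C is the mean local clustering
# (unweighted, to match the unweighted null), L the characteristic path
# length on the largest component.
smallWorldIndex <- function(g, nullReplicates = 100L, seed = 1L,
                            useTransitivity = FALSE) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m == 0 || n < 3) return(NA_real_)
  gu <- igraph::delete_edge_attr(g, "weight")
  cObs <- if (useTransitivity) {
    igraph::transitivity(gu, type = "global")
  } else {
    mean(igraph::transitivity(gu, type = "localundirected", isolates = "zero"))
  }
  lObs <- largestComponentPaths(gu)$cpl
  set.seed(as.integer(seed))
  cNull <- numeric(nullReplicates)
  lNull <- numeric(nullReplicates)
  for (r in seq_len(nullReplicates)) {
    gr <- igraph::sample_gnm(n, m)
    cNull[r] <- if (useTransitivity) {
      igraph::transitivity(gr, type = "global")
    } else {
      mean(igraph::transitivity(gr, type = "localundirected", isolates = "zero"))
    }
    lNull[r] <- largestComponentPaths(gr)$cpl
  }
  cRand <- mean(cNull, na.rm = TRUE)
  lRand <- mean(lNull, na.rm = TRUE)
  if (!is.finite(cRand) || cRand == 0 || !is.finite(lRand) || lRand == 0 ||
      !is.finite(lObs)) {
    return(NA_real_)
  }
  (cObs / cRand) / (lObs / lRand)
}

#' Topology summary of a physiological network
#'
#' The full battery: Krackhardt connectedness (fraction of node pairs joined
#' by a path), density, mean weighted local clustering (Onnela/Fagiolo, with
#' weights rescaled by the maximum), weighted Newman modularity of the
#' supplied (or Louvain) partition, small-world index against an
#' Erdos-Renyi G(n, m) null, global efficiency, characteristic path length
#' and diameter (unweighted, on the largest connected component), and Freeman
#' betweenness centralization.
#'
#' Path-based metrics treat the thresholded graph as unweighted: the rho^2
#' weights are similarities, not traversal costs, and hop-count diameters are
#' what the battery reports.
#'
#' @param net a [PhysioNetwork-class] (or igraph).
#' @param partition optional [Partition-class]; if missing, the Louvain
#'   partition of `net` is used for modularity.
#' @param swReplicates Erdos-Renyi replicates for the small-world null
#'   (default 100).
#' @param seed seed for the small-world null and (if needed) Louvain.
#' @return named list of the nine metrics.
#' @export
topologySummary <- function(net, partition = NULL, swReplicates = 100L,
                            seed = 1L) {
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes")
  if (is.null(partition)) partition <- louvainPartition(net, seed = seed)
  stopifnot(is(partition, "Partition"))
  memb <- partitionMembership(partition)
  if (!all(igraph::V(g)$name %in% names(memb))) {
    stop("partition does not cover all nodes")
  }
  mod <- if (igraph::ecount(g) == 0) 0 else {
    igraph::modularity(g, memb[igraph::V(g)$name],
                       weights = igraph::E(g)$weight)
  }
  paths <- largestComponentPaths(g)
  list(
    connectedness = krackhardtConnectedness(g),
    density = igraph::edge_density(g),
    clustering_coefficient = weightedClustering(g),
    modularity = mod,
    small_world_index = smallWorldIndex(g, swReplicates, seed),
    efficiency = globalEfficiency(g),
    characteristic_path_length = paths$cpl,
    diameter = paths$diameter,
    freeman_betweenness_centralization = freemanBetweennessCentralization(g)
  )
}

#' Node centralities
#'
#' Eigencentrality of the weighted adjacency (leading eigenvector, rescaled to
#' maximum 1), shortest-path betweenness on the unweighted thresholded graph,
#' degree, and strength (sum of incident rho^2 weights).
#'
#' @param net a [PhysioNetwork-class] (or igraph).
#' @return data.frame with columns `node`, `eigencentrality`, `betweenness`,
#'   `degree`, `strength`.
#' @export
nodeCentralities <- function(net) {
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  ev <- if (igraph::ecount(g) == 0) {
    rep(0, igraph::vcount(g))
  } else {
    # leading eigenvector of the weighted adjacency, dense symmetric solve:
    # deterministic (no random restarts) and exact on these small graphs
    A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
    v[v < .Machine$double.eps^0.75] <- 0
    v / max(v)
  }
  data.frame(
    node = igraph::V(g)$name,
    eigencentrality = unname(ev),
    betweenness = unname(igraph::betweenness(g, weights = NA,
                                             directed = FALSE)),
    degree = unname(igraph::degree(g)),
    strength = unname(igraph::strength(g, weights = igraph::E(g)$weight)),
    row.names = NULL)
}

#' Assortativity of a node attribute over edges
#'
#' Pearson correlation of the attribute values at the two endpoints of every
#' edge, with each edge counted in both orientations: positive when nodes of
#' similar value link together.
#'
#' @param net a [PhysioNetwork-class] (or igraph) with at least one edge.
#' @param values named numeric vector of node values (names = node ids).
#' @return the assortativity coefficient.
#' @export
centralityAssortativity <- function(net, values) {
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  if (igraph::ecount(g) == 0) stop("need at least one edge")
  el <- igraph::as_edgelist(g)
  a <- values[el[, 1]]
  b <- values[el[, 2]]
  x <- c(a, b)
  y <- c(b, a)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("assortativity undefined for constant values")
  }
  cor(x, y)
}

#' Hierarchy layers from the most influential node
#'
#' Roots the hierarchy at the node of maximal eigencentrality (ties broken by
#' strength, then lexicographic id). Cycles are broken by repeatedly removing
#' the weakest edge that still lies on a cycle (reverse-delete), which leaves
#' the maximum-weight spanning forest; nodes are then layered by their graph
#' distance from the root in that forest. Nodes in other components (e.g. an
#' isolated variable) carry `NA` and are flagged unreachable.
#'
#' @param net a [PhysioNetwork-class] (or igraph).
#' @return list with `root`, `layers` (named integer vector, root = 0, `NA`
#'   when unreachable), and `unreachable` (character vector of node ids).
#' @export
hierarchyLayers <- function(net) {
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  cent <- nodeCentralities(net)
  ord <- order(-cent$eigencentrality, -cent$strength, cent$node)
  root <- cent$node[ord[1]]
  forest <- if (igraph::ecount(g) > 0) {
    # minimum spanning forest on reversed weights = maximum-weight forest,
    # identical to reverse-deleting the weakest cyclic edge first
    w <- igraph::E(g)$weight
    igraph::mst(g, weights = max(w) + 1 - w)
  } else {
    g
  }
  d <- igraph::distances(forest, v = root, weights = NA)[1, ]
  layers <- ifelse(is.finite(d), d, NA_real_)
  layers <- setNames(as.integer(layers), igraph::V(forest)$name)
  list(root = root, layers = layers,
       unreachable = names(layers)[is.na(layers)])
}

#' Compare degree distributions of two networks
#'
#' Two-sample Kolmogorov-Smirnov test on the node degree sequences.
#'
#' @param netA,netB [PhysioNetwork-class] (or igraph) objects.
#' @return list with `D` (KS statistic) and `p` (asymptotic p-value).
#' @export
compareDegreeDistributions <- function(netA, netB) {
  dA <- igraph::degree(networkGraph(asPhysioNetwork(netA)))
  dB <- igraph::degree(networkGraph(asPhysioNetwork(netB)))
  ks <- suppressWarnings(ks.test(dA, dB))
  list(D = unname(ks$statistic), p = ks$p.value)
}
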