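# Community detection (Louvain, Spinglass), partition comparison
# (VI / NMI / Rand) and cluster contraction.

partitionFromMembership <- function(memb, net, method) {
  g <- networkGraph(net)
  memb <- as.integer(factor(memb, levels = sort(unique(memb))))
  names(memb) <- igraph::V(g)$name
  mod <- if (igraph::ecount(g) == 0) 0 else {
    igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  }
  new("Partition", membership = memb, method = method, modularity = mod)
}

#' Louvain community detection
#'
#' Two-phase heuristic maximization of the weighted Newman modularity.
#' Seeded for reproducibility; an edgeless graph yields the singleton
#' partition with modularity 0.
#'
#' @param net a [PhysioNetwork-class] (or igraph).
#' @param seed integer RNG seed.
#' @return a [Partition-class].
#' @export
louvainPartition <- function(net, seed = 1L) {
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  if (igraph::ecount(g) == 0) {
    return(partitionFromMembership(seq_len(igraph::vcount(g)), net, "louvain"))
  }
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  partitionFromMembership(igraph::membership(cl), net, "louvain")
}

#' Spinglass community detection
#'
#' Potts-model simulated-annealing community assignment (Reichardt-Bornholdt
#' energy with edge weights). The algorithm is defined per connected
#' component; disconnected graphs are handled by running it independently on
#' every component (isolated nodes become singleton clusters).
#'
#' @param net a [PhysioNetwork-class] (or igraph).
#' @param nSpins maximum number of spins/communities (default 25).
#' @param gamma energy parameter balancing present vs absent edges
#'   (default 1).
#' @param seed integer RNG seed.
#' @return a [Partition-class].
#' @export
spinglassPartition <- function(net, nSpins = 25L, gamma = 1.0, seed = 1L) {
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  n <- igraph::vcount(g)
  memb <- integer(n)
  comp <- igraph::components(g)
  set.seed(as.integer(seed))
  offset <- 0L
  for (k in seq_len(comp$no)) {
    vk <- which(comp$membership == k)
    if (length(vk) == 1L || sum(comp$membership == k) < 2 ||
        igraph::ecount(igraph::induced_subgraph(g, vk)) == 0) {
      memb[vk] <- offset + seq_along(vk)
      offset <- offset + length(vk)
      next
    }
    sub <- igraph::induced_subgraph(g, vk)
    cl <- igraph::cluster_spinglass(sub, weights = igraph::E(sub)$weight,
                                    spins = min(nSpins, igraph::vcount(sub)),
                                    gamma = gamma)
    m <- igraph::membership(cl)
    memb[vk] <- offset + as.integer(m)
    offset <- offset + max(m)
  }
  partitionFromMembership(memb, net, "spinglass")
}

#' Construct a manual partition
#'
#' @param membership named vector of cluster labels (names = node ids).
#' @param net the [PhysioNetwork-class] the partition refers to (used to
#'   compute its modularity).
#' @return a [Partition-class].
#' @export
manualPartition <- function(membership, net) {
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  stopifnot(setequal(names(membership), igraph::V(g)$name))
  partitionFromMembership(membership[igraph::V(g)$name], net, "manual")
}

# Contingency counts of two label vectors over the same items.
partitionContingency <- function(a, b) table(a, b)

#' Distance and agreement between two partitions
#'
#' From the pair-counting / information-theoretic contingency of the two
#' labelings: variation of information `VI = H(A) + H(B) - 2 I(A, B)` in
#' bits, normalized mutual information `NMI = 2 I / (H(A) + H(B))` (1 for a
#' pair of identical partitions, and by convention also when both partitions
#' are the single all-in-one block), and the Rand index, the fraction of
#' node pairs on which the partitions agree.
#'
#' @param p,q [Partition-class] objects (or named label vectors) over the
#'   same node set.
#' @return list with `variation_of_information` (bits),
#'   `normalized_mutual_information`, `rand_index`.
#' @export
partitionDistance <- function(p, q) {
  a <- if (is(p, "Partition")) partitionMembership(p) else p
  b <- if (is(q, "Partition")) partitionMembership(q) else q
  if (!setequal(names(a), names(b))) stop("partitions cover different nodes")
  b <- b[names(a)]
  n <- length(a)
  tab <- partitionContingency(a, b)
  pj <- rowSums(tab) / n
  qk <- colSums(tab) / n
  pr <- tab / n
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  hA <- ent(pj)
  hB <- ent(qk)
  nz <- pr > 0
  mi <- sum(pr[nz] * log2(pr[nz] / (pj[row(pr)[nz]] * qk[col(pr)[nz]])))
  vi <- hA + hB - 2 * mi
  nmi <- if (hA + hB == 0) 1 else 2 * mi / (hA + hB)
  # Rand: agreeing pairs (together in both or apart in both) over all pairs
  sumSqTab <- sum(tab^2)
  sumSqA <- sum(rowSums(tab)^2)
  sumSqB <- sum(colSums(tab)^2)
  pairs <- n * (n - 1) / 2
  together <- (sumSqTab - n) / 2
  aApart <- (sumSqA - n) / 2
  bApart <- (sumSqB - n) / 2
  rand <- (pairs + 2 * together - aApart - bApart) / pairs
  list(variation_of_information = max(vi, 0),
       normalized_mutual_information = nmi,
       rand_index = rand)
}

#' Contract clusters into a cluster network
#'
#' Collapses every cluster onto its representative, the member of greatest
#' eigencentrality (ties broken by strength, then id). Edges between two
#' clusters aggregate the weights of all original inter-cluster edges;
#' intra-cluster edges are dropped. The representative's centralities are
#' reported on the cluster node.
#'
#' @param net a [PhysioNetwork-class] (or igraph).
#' @param partition a [Partition-class] covering `net`.
#' @param centralities optional data.frame from [nodeCentralities()]
#'   (recomputed if missing).
#' @return list with `graph` (igraph of cluster nodes, named by
#'   representative, edge attribute `weight`) and `representatives` (named
#'   character vector cluster -> representative node).
#' @export
contractClusters <- function(net, partition, centralities = NULL) {
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  stopifnot(is(partition, "Partition"))
  memb <- partitionMembership(partition)[igraph::V(g)$name]
  if (anyNA(memb)) stop("partition does not cover the network")
  if (is.null(centralities)) centralities <- nodeCentralities(net)
  reps <- vapply(seq_len(max(memb)), function(k) {
    members <- names(memb)[memb == k]
    sub <- centralities[centralities$node %in% members, ]
    sub <- sub[order(-sub$eigencentrality, -sub$strength, sub$node), ]
    sub$node[1]
  }, character(1))
  cg <- igraph::make_empty_graph(n = length(reps), directed = FALSE)
  cg <- igraph::set_vertex_attr(cg, "name", value = reps)
  ci <- centralities[match(reps, centralities$node), ]
  cg <- igraph::set_vertex_attr(cg, "eigencentrality",
                                value = ci$eigencentrality)
  cg <- igraph::set_vertex_attr(cg, "betweenness", value = ci$betweenness)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    ka <- memb[el[, 1]]
    kb <- memb[el[, 2]]
    cross <- ka != kb
    if (any(cross)) {
      lo <- pmin(ka[cross], kb[cross])
      hi <- pmax(ka[cross], kb[cross])
      w <- igraph::E(g)$weight[cross]
      agg <- tapply(w, paste(lo, hi), sum)
      pairIds <- do.call(rbind, strsplit(names(agg), " "))
      edges <- rbind(reps[as.integer(pairIds[, 1])],
                     reps[as.integer(pairIds[, 2])])
      cg <- igraph::add_edges(cg, edges)
      cg <- igraph::set_edge_attr(cg, "weight", value = as.numeric(agg))
    }
  }
  list(graph = cg, representatives = setNames(reps, seq_along(reps)))
}

#' Angular eigenvector ordering of variables
#'
#' Utility for heatmap display: orders variables by the angle
#' `atan2(PC2, PC1)` of their loadings on the first two principal components
#' of the correlation matrix, placing similar variables contiguously.
#'
#' @param corr a [CorrelationMatrix-class].
#' @return character vector of variable ids in angular order.
#' @export
angularOrder <- function(corr) {
  stopifnot(is(corr, "CorrelationMatrix"))
  r <- corr@rho
  r[is.na(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2
  eig <- eigen(r, symmetric = TRUE)
  ang <- atan2(eig$vectors[, 2], eig$vectors[, 1])
  colnames(r)[order(ang)]
}
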