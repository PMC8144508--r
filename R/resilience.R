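# Attack simulations, connectivity-loss curves and the differential network.

# Number of unordered node pairs joined by a path.
connectedPairs <- function(g) {
  sizes <- igraph::components(g)$csize
  sum(sizes * (sizes - 1) / 2)
}

#' Connectivity loss after node removal
#'
#' `1 - (connected pairs in the residual graph) / (connected pairs in the
#' intact graph)`, where a connected pair is an unordered node pair joined by
#' some path (reachable-pair semantics). 0 with nothing removed, 1 with all
#' nodes removed.
#'
#' @param net a [PhysioNetwork-class] (or igraph).
#' @param removed character vector of node ids to remove.
#' @return loss in \[0, 1\].
#' @export
connectivityLoss <- function(net, removed) {
  g <- networkGraph(asPhysioNetwork(net))
  base <- connectedPairs(g)
  if (base == 0) stop("intact graph has no connected pairs")
  stopifnot(all(removed %in% igraph::V(g)$name))
  res <- igraph::delete_vertices(g, removed)
  1 - connectedPairs(res) / base
}

# Deterministic ordering helper: descending metric, ties by descending
# strength then lexicographic id.
orderNodes <- function(metric, strength, ids) {
  ids[order(-metric, -strength, ids)]
}

#' Attack a network and record its connectivity-loss curve
#'
#' Removal strategies:
#' * `random` — uniformly random order, loss averaged over `nRandomReps`
#'   replicates (seeded);
#' * `degree` / `betweenness` — nodes removed in descending order of the
#'   metric computed once on the intact graph;
#' * `cascading` — betweenness recomputed on the residual graph after every
#'   removal, always removing the current maximum.
#'
#' Ties everywhere break by node strength (descending), then lexicographic
#' id. Loss is recorded after each removal; it is non-decreasing and reaches
#' 1 when all nodes are gone.
#'
#' @param net a [PhysioNetwork-class] (or igraph).
#' @param strategy one of `"random"`, `"degree"`, `"betweenness"`,
#'   `"cascading"`.
#' @param seed RNG seed for the random strategy.
#' @param nRandomReps random-order replicates to average (default 100).
#' @param recompute logical; for `degree`/`betweenness`, recompute the metric
#'   on the residual graph after every removal (default FALSE:
#'   initial-metric order).
#' @return list with `strategy`, `loss` (numeric vector, one value per
#'   removal), `removal_order` (node ids; for `random`, the order of the
#'   first replicate), `n` (node count), and for random `n_random_reps` and
#'   `seed`.
#' @export
attackNetwork <- function(net, strategy = c("random", "degree", "betweenness",
                                            "cascading"),
                          seed = 1L, nRandomReps = 100L, recompute = FALSE) {
  strategy <- match.arg(strategy)
  net <- asPhysioNetwork(net)
  g <- networkGraph(net)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty network")
  ids <- igraph::V(g)$name
  strength <- igraph::strength(g, weights = igraph::E(g)$weight)
  base <- connectedPairs(g)
  if (base == 0) stop("intact graph has no connected pairs")

  lossOfOrder <- function(ord) {
    res <- g
    unname(vapply(ord, function(v) {
      res <<- igraph::delete_vertices(res, v)
      1 - connectedPairs(res) / base
    }, numeric(1)))
  }

  if (strategy == "random") {
    set.seed(as.integer(seed))
    acc <- matrix(0, nrow = nRandomReps, ncol = n)
    firstOrder <- NULL
    for (r in seq_len(nRandomReps)) {
      ord <- sample(ids)
      if (r == 1L) firstOrder <- ord
      acc[r, ] <- lossOfOrder(ord)
    }
    return(list(strategy = strategy, loss = colMeans(acc),
                removal_order = firstOrder, n = n,
                n_random_reps = nRandomReps, seed = as.integer(seed)))
  }

  if (strategy %in% c("degree", "betweenness") && !recompute) {
    metric <- if (strategy == "degree") {
      igraph::degree(g)
    } else {
      igraph::betweenness(g, weights = NA, directed = FALSE)
    }
    ord <- orderNodes(metric, strength, ids)
    return(list(strategy = strategy, loss = lossOfOrder(ord),
                removal_order = ord, n = n))
  }

  # recomputed-metric attacks (cascading = recomputed betweenness)
  metricFun <- switch(strategy,
    cascading = ,
    betweenness = function(h) igraph::betweenness(h, weights = NA,
                                                  directed = FALSE),
    degree = function(h) igraph::degree(h))
  res <- g
  ord <- character(0)
  loss <- numeric(0)
  while (igraph::vcount(res) > 0) {
    m <- metricFun(res)
    vids <- igraph::V(res)$name
    st <- strength[vids]
    pick <- orderNodes(m, st, vids)[1]
    res <- igraph::delete_vertices(res, pick)
    ord <- c(ord, pick)
    loss <- c(loss, 1 - connectedPairs(res) / base)
  }
  list(strategy = strategy, loss = loss, removal_order = ord, n = n)
}

#' Smallest removed fraction reaching a target connectivity loss
#'
#' @param curve an attack curve from [attackNetwork()].
#' @param targetLoss target loss in (0, 1\].
#' @return the smallest k/n whose recorded loss is >= `targetLoss`.
#' @export
removalFractionForLoss <- function(curve, targetLoss) {
  stopifnot(targetLoss > 0, targetLoss <= 1)
  k <- which(curve$loss >= targetLoss - 1e-12)[1]
  if (is.na(k)) stop("target loss never reached")
  k / curve$n
}

#' Differential network of two cohorts
#'
#' Superimposes two networks over the shared variable universe and classifies
#' every edge of either as `shared`, `a_only` or `b_only`; the three sets are
#' disjoint and their union is the union of both edge sets.
#'
#' @param netA,netB [PhysioNetwork-class] (or igraph) objects with comparable
#'   node names.
#' @return list with `edges` (data.frame `var_a`, `var_b`, `origin`,
#'   `weight_a`, `weight_b`), `counts` (named vector: shared, a_only, b_only,
#'   total), and `graph` (igraph with edge attribute `origin`).
#' @export
differentialNetwork <- function(netA, netB) {
  gA <- networkGraph(asPhysioNetwork(netA))
  gB <- networkGraph(asPhysioNetwork(netB))
  edgeKeys <- function(g) {
    if (igraph::ecount(g) == 0) {
      return(data.frame(var_a = character(), var_b = character(),
                        weight = numeric(), key = character()))
    }
    el <- igraph::as_edgelist(g)
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    data.frame(var_a = a, var_b = b, weight = igraph::E(g)$weight,
               key = paste(a, b, sep = "|"))
  }
  eA <- edgeKeys(gA)
  eB <- edgeKeys(gB)
  allKeys <- union(eA$key, eB$key)
  inA <- allKeys %in% eA$key
  inB <- allKeys %in% eB$key
  origin <- ifelse(inA & inB, "shared", ifelse(inA, "a_only", "b_only"))
  split <- do.call(rbind, strsplit(allKeys, "|", fixed = TRUE))
  edges <- data.frame(
    var_a = if (length(allKeys)) split[, 1] else character(),
    var_b = if (length(allKeys)) split[, 2] else character(),
    origin = origin,
    weight_a = eA$weight[match(allKeys, eA$key)],
    weight_b = eB$weight[match(allKeys, eB$key)])
  counts <- c(shared = sum(origin == "shared"),
              a_only = sum(origin == "a_only"),
              b_only = sum(origin == "b_only"),
              total = length(allKeys))
  nodes <- union(igraph::V(gA)$name, igraph::V(gB)$name)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (length(allKeys)) {
    g <- igraph::add_edges(g, rbind(edges$var_a, edges$var_b))
    g <- igraph::set_edge_attr(g, "origin", value = edges$origin)
  }
  list(edges = edges, counts = counts, graph = g)
}
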