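# Subsampled-network ensemble protocol, metric-wise Mann-Whitney comparison,
# and paired node-centrality tests across two cohort networks.

#' Build an ensemble of networks from random cohort subsamples
#'
#' For each replicate, draws `subsampleSize` subjects without replacement,
#' rebuilds the Spearman correlation matrix, thresholds it into a network and
#' computes the topology battery. Replicate seeds derive from the master seed
#' by fixed increments, so draws are independent across replicates and the
#' whole ensemble is reproducible.
#'
#' @param cohort a normalized [PhysioCohort-class].
#' @param nNetworks number of replicate networks (default 30).
#' @param subsampleSize subjects per replicate (default 60).
#' @param seed master RNG seed.
#' @param pThreshold significance threshold for edges (default 0.05).
#' @param swReplicates Erdos-Renyi replicates for the small-world null of
#'   each summary (default 100).
#' @param label cohort label carried in the result.
#' @return list with `label`, `n_networks`, `subsample_size`, `seed`, and
#'   `summaries` (data.frame, one row per replicate, columns = metrics).
#' @export
subsampleNetworks <- function(cohort, nNetworks = 30L, subsampleSize = 60L,
                              seed = 1L, pThreshold = 0.05,
                              swReplicates = 100L, label = "") {
  stopifnot(is(cohort, "PhysioCohort"))
  n <- nrow(cohortValues(cohort))
  if (n < subsampleSize) stop("cohort smaller than the subsample size")
  rows <- lapply(seq_len(nNetworks), function(r) {
    repSeed <- as.integer(seed) + r - 1L
    set.seed(repSeed)
    sub <- subsetSubjects(cohort, sort(sample(n, subsampleSize)))
    net <- cohortNetwork(sub, pThreshold = pThreshold)
    as.data.frame(topologySummary(net, swReplicates = swReplicates,
                                  seed = repSeed))
  })
  list(label = label, n_networks = as.integer(nNetworks),
       subsample_size = as.integer(subsampleSize), seed = as.integer(seed),
       summaries = do.call(rbind, rows))
}

#' Compare two subsample ensembles metric by metric
#'
#' Per topology metric: group means and SDs plus a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test of the replicate values (normal approximation
#' with tie correction by default; exact for small samples without ties).
#'
#' @param a,b ensembles from [subsampleNetworks()].
#' @return data.frame with columns `metric`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `U`, `p`.
#' @export
compareEnsembles <- function(a, b) {
  sa <- a$summaries
  sb <- b$summaries
  stopifnot(nrow(sa) > 0, nrow(sb) > 0)
  metrics <- intersect(names(sa), names(sb))
  rows <- lapply(metrics, function(m) {
    x <- sa[[m]]
    y <- sb[[m]]
    ok <- is.finite(x) & !is.na(x)
    ok2 <- is.finite(y) & !is.na(y)
    x <- x[ok]
    y <- y[ok2]
    if (length(x) == 0 || length(y) == 0) {
      return(data.frame(metric = m, mean_a = NA, sd_a = NA, mean_b = NA,
                        sd_b = NA, U = NA, p = NA))
    }
    wt <- suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE))
    data.frame(metric = m, mean_a = mean(x), sd_a = sd(x),
               mean_b = mean(y), sd_b = sd(y),
               U = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired centrality tests between two networks
#'
#' Matches nodes by variable id across the two networks and, per centrality
#' (eigencentrality, betweenness, strength), reports the Wilcoxon
#' matched-pairs signed-rank statistic in the signed-rank-sum convention
#' (`W = sum of signed ranks of the non-zero differences a - b`; 0 when the
#' networks agree) with its two-sided p-value, and the Spearman rank
#' correlation of the paired values with its p-value.
#'
#' @param netA,netB [PhysioNetwork-class] (or igraph) objects sharing a node
#'   universe.
#' @return data.frame with columns `centrality`, `wilcoxon_W`, `p_w`,
#'   `spearman_rho`, `p_s`, `n`.
#' @export
pairedCentralityTests <- function(netA, netB) {
  cA <- nodeCentralities(asPhysioNetwork(netA))
  cB <- nodeCentralities(asPhysioNetwork(netB))
  shared <- intersect(cA$node, cB$node)
  if (length(shared) < 3) stop("need at least 3 shared nodes")
  cA <- cA[match(shared, cA$node), ]
  cB <- cB[match(shared, cB$node), ]
  rows <- lapply(c("eigencentrality", "betweenness", "strength"), function(m) {
    x <- cA[[m]]
    y <- cB[[m]]
    d <- x - y
    nz <- d != 0
    if (any(nz)) {
      rk <- rank(abs(d[nz]))
      W <- sum(sign(d[nz]) * rk)
      pw <- suppressWarnings(wilcox.test(x, y, paired = TRUE))$p.value
    } else {
      W <- 0
      pw <- 1
    }
    r <- spearmanRho(x, y)
    ps <- spearmanP(r, length(x))
    data.frame(centrality = m, wilcoxon_W = W, p_w = pw,
               spearman_rho = r, p_s = ps, n = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of hierarchy layers across two networks
#'
#' Matches nodes by id and correlates their [hierarchyLayers()] depths
#' (nodes unreachable in either network are dropped).
#'
#' @param netA,netB [PhysioNetwork-class] (or igraph) objects.
#' @return list with `rho`, `p`, `n`.
#' @export
hierarchyCorrelation <- function(netA, netB) {
  hA <- hierarchyLayers(asPhysioNetwork(netA))$layers
  hB <- hierarchyLayers(asPhysioNetwork(netB))$layers
  shared <- intersect(names(hA), names(hB))
  x <- hA[shared]
  y <- hB[shared]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 shared reachable nodes")
  r <- spearmanRho(x[ok], y[ok])
  list(rho = r, p = spearmanP(r, sum(ok)), n = sum(ok))
}
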