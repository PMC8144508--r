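# Spearman correlation matrix under pairwise deletion and its thresholding
# into a weighted undirected physiological network.

# Spearman rho of two complete vectors via midranks; NA if degenerate.
spearmanRho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sx <- sd(rx)
  sy <- sd(ry)
  if (sx == 0 || sy == 0) return(NA_real_)
  # ratio of rank covariance to the product of rank standard deviations
  stats::cov(rx, ry) / (sx * sy)
}

# Two-sided p for Spearman rho via the Student t approximation on n-2 df.
spearmanP <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Spearman correlation matrix with pairwise deletion
#'
#' For every unordered pair of variables the Spearman rank correlation is
#' computed on the rows where both are observed (pairwise deletion, no
#' imputation), using midranks for ties; significance comes from the Student t
#' approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom, two-sided. Pairs with fewer than `minPairs` joint observations
#' (or a constant margin) are undefined.
#'
#' @param cohort a [PhysioCohort-class] or numeric matrix (subjects x
#'   variables; `NA` = missing).
#' @param minPairs minimum joint observations to define an entry (default 3).
#' @return a [CorrelationMatrix-class].
#' @export
spearmanMatrix <- function(cohort, minPairs = 3L) {
  vals <- if (is(cohort, "PhysioCohort")) cohortValues(cohort) else as.matrix(cohort)
  p <- ncol(vals)
  if (p < 2L) stop("need at least 2 variables")
  vars <- colnames(vals)
  rho <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  pv <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  nm <- matrix(0L, p, p, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(pv) <- 0
  obs <- !is.na(vals)
  diag(nm) <- colSums(obs)
  complete <- all(obs)
  if (complete) {
    # fast path: rank once, Pearson on ranks
    rk <- apply(vals, 2, rank)
    rmat <- suppressWarnings(cor(rk))
    n <- nrow(vals)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        r <- rmat[i, j]
        if (is.na(r)) r <- NA_real_
        rho[i, j] <- rho[j, i] <- r
        pv[i, j] <- pv[j, i] <- spearmanP(r, n)
        nm[i, j] <- nm[j, i] <- n
      }
    }
  } else {
    for (i in seq_len(p - 1)) {
      xi <- vals[, i]
      oi <- obs[, i]
      for (j in (i + 1):p) {
        ok <- oi & obs[, j]
        n <- sum(ok)
        nm[i, j] <- nm[j, i] <- n
        if (n < minPairs) next
        r <- spearmanRho(xi[ok], vals[ok, j])
        rho[i, j] <- rho[j, i] <- r
        pv[i, j] <- pv[j, i] <- spearmanP(r, n)
      }
    }
  }
  new("CorrelationMatrix", rho = rho, p = pv, n = nm,
      minPairs = as.integer(minPairs))
}

#' Long-format table of a correlation matrix
#'
#' @param corr a [CorrelationMatrix-class].
#' @return data.frame `var_a`, `var_b`, `rho`, `p`, `n_eff`, one row per
#'   unordered pair.
#' @export
correlationTable <- function(corr) {
  stopifnot(is(corr, "CorrelationMatrix"))
  vars <- colnames(corr@rho)
  idx <- which(upper.tri(corr@rho), arr.ind = TRUE)
  data.frame(var_a = vars[idx[, 1]], var_b = vars[idx[, 2]],
             rho = corr@rho[idx], p = corr@p[idx], n_eff = corr@n[idx])
}

#' Threshold a correlation matrix into a physiological network
#'
#' An edge joins two variables iff their correlation is defined and its
#' p-value is below the threshold (no multiple-testing correction by default,
#' optionally Benjamini-Hochberg). Edge weight is the squared correlation
#' rho^2, making all weights positive; the sign of the original rho is kept
#' as an edge attribute. The result is weighted and undirected, one node per
#' variable (including isolated ones).
#'
#' An optional row-bootstrap stability filter keeps only edges that reappear
#' (significant, same criteria) in at least a fraction `stabilityQ` of `B`
#' bootstrap resamples of the subjects; it requires passing the originating
#' cohort.
#'
#' @param corr a [CorrelationMatrix-class].
#' @param pThreshold significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg.
#' @param bootstrap optional list `list(cohort =, B =, q =, seed =)` enabling
#'   the row-bootstrap edge-stability filter.
#' @return a [PhysioNetwork-class].
#' @export
buildNetwork <- function(corr, pThreshold = 0.05, adjust = c("none", "BH"),
                         bootstrap = NULL) {
  stopifnot(is(corr, "CorrelationMatrix"))
  adjust <- match.arg(adjust)
  vars <- colnames(corr@rho)
  idx <- which(upper.tri(corr@rho), arr.ind = TRUE)
  rho <- corr@rho[idx]
  pv <- corr@p[idx]
  ne <- corr@n[idx]
  if (adjust == "BH") {
    def <- !is.na(pv)
    pv[def] <- p.adjust(pv[def], method = "BH")
  }
  keep <- !is.na(rho) & !is.na(pv) & pv < pThreshold & rho != 0
  if (!is.null(bootstrap)) {
    keep <- keep & bootstrapStableEdges(bootstrap, vars, idx, pThreshold,
                                        adjust, corr@minPairs)
  }
  el <- cbind(vars[idx[keep, 1]], vars[idx[keep, 2]])
  g <- igraph::make_empty_graph(n = length(vars), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vars)
  if (nrow(el) > 0) {
    g <- igraph::add_edges(g, t(el))
    g <- igraph::set_edge_attr(g, "weight", value = rho[keep]^2)
    g <- igraph::set_edge_attr(g, "sign", value = sign(rho[keep]))
    g <- igraph::set_edge_attr(g, "rho", value = rho[keep])
    g <- igraph::set_edge_attr(g, "p", value = pv[keep])
    g <- igraph::set_edge_attr(g, "n_eff", value = ne[keep])
  }
  new("PhysioNetwork", graph = g, pThreshold = pThreshold)
}

# Row-bootstrap edge stability: fraction of B resamples in which each pair is
# significant again; TRUE where fraction >= q.
bootstrapStableEdges <- function(bootstrap, vars, idx, pThreshold, adjust,
                                 minPairs) {
  cohort <- bootstrap$cohort
  B <- if (is.null(bootstrap$B)) 100L else as.integer(bootstrap$B)
  q <- if (is.null(bootstrap$q)) 0.5 else bootstrap$q
  set.seed(if (is.null(bootstrap$seed)) 1L else as.integer(bootstrap$seed))
  vals <- if (is(cohort, "PhysioCohort")) cohortValues(cohort) else as.matrix(cohort)
  stopifnot(identical(colnames(vals), vars))
  hits <- numeric(nrow(idx))
  for (b in seq_len(B)) {
    rows <- sample(nrow(vals), replace = TRUE)
    cb <- spearmanMatrix(vals[rows, , drop = FALSE], minPairs = minPairs)
    pv <- cb@p[idx]
    if (adjust == "BH") {
      def <- !is.na(pv)
      pv[def] <- p.adjust(pv[def], method = "BH")
    }
    hits <- hits + (!is.na(pv) & pv < pThreshold)
  }
  hits / B >= q
}

#' Build the physiological network straight from a cohort
#'
#' Convenience chaining of [spearmanMatrix()] and [buildNetwork()].
#'
#' @inheritParams spearmanMatrix
#' @inheritParams buildNetwork
#' @return a [PhysioNetwork-class].
#' @export
cohortNetwork <- function(cohort, pThreshold = 0.05, minPairs = 3L,
                          adjust = c("none", "BH")) {
  buildNetwork(spearmanMatrix(cohort, minPairs = minPairs),
               pThreshold = pThreshold, adjust = match.arg(adjust))
}

#' Write a network as GraphML
#'
#' @param net a [PhysioNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetworkGraphML <- function(net, path) {
  igraph::write_graph(networkGraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a network as a weighted edge-list TSV
#'
#' Columns: `var_a`, `var_b`, `weight`, `sign`, `rho`, `p`, `n_eff`.
#'
#' @inheritParams writeNetworkGraphML
#' @return `path`, invisibly.
#' @export
writeNetworkEdgeList <- function(net, path) {
  write.table(networkEdges(net), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
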