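# Shared in-code fixtures for the test suite.

# Tiny two-sided range table.
tinyRanges <- function(fallback = "data_range") {
  ClinicalRangeTable(data.frame(
    variable_id = c("P0", "P0", "H8", "H8", "M5"),
    sex = c("M", "F", "M", "F", "both"),
    min = c(90, 90, 14.9, 12, 70),
    max = c(120, 120, 18.7, 16, 100)),
    fallbackPolicy = fallback)
}

# Small raw cohort on the tinyRanges variables.
tinyCohort <- function(values = NULL) {
  if (is.null(values)) {
    values <- rbind(
      c(100, 16, 80),
      c(110, 15, 95),
      c(95, 14, 85),
      c(118, 15.5, 75))
  }
  colnames(values) <- c("P0", "H8", "M5")
  rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  PhysioCohort(values, sex = rep(c("M", "F"), length.out = nrow(values)))
}

# igraph helper: weighted undirected graph from an edge data.frame.
edgeGraph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  g
}

# Independent pair-connectivity oracle: counts unordered connected pairs by
# boolean reachability closure on the adjacency matrix (no igraph).
connectedPairsOracle <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  reach <- (adj | diag(TRUE, n))
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  (sum(reach) - n) / 2
}

# Brute-force Spearman for tie-free vectors: 1 - 6 sum d^2 / (n (n^2-1)).
spearmanNoTiesOracle <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A small planted-block cohort spec for community recovery tests.
plantedBlockSpec <- function(nPerBlock = 5, nBlocks = 4, n = 200,
                             within = 0.6, between = 0.1, seed = 1) {
  vars <- sprintf("V%02d", seq_len(nPerBlock * nBlocks))
  cohortSpec(
    nSubjects = c(M = n),
    blocks = data.frame(variable_id = vars,
                        block = rep(sprintf("B%d", seq_len(nBlocks)),
                                    each = nPerBlock)),
    withinRho = within, betweenRho = between,
    missingRate = 0, seed = seed)
}
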