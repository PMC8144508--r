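# End-to-end orchestration: normalization, health filter, balancing, per-sex
# networks and their comparison, with all artifacts written to disk and a
# manifest recording seeds and thresholds.

#' Run the full physiological-network pipeline
#'
#' Sequences the whole analysis for a two-sex biomarker cohort: clinical-range
#' normalization, the health filter (exclude any subject with a normalized
#' value outside \[0, 1\]), optional group-size balancing, per-sex Spearman
#' correlation matrices and thresholded networks, topology summaries,
#' Louvain partitions, cluster networks, hierarchy layers and attack curves;
#' then the cross-sex differential network, paired centrality tests,
#' hierarchy correlation, degree-distribution comparison and the subsampled
#' ensemble comparison.
#'
#' @param cohort a raw [PhysioCohort-class] (or path to a cohort CSV).
#' @param rangeTable a [ClinicalRangeTable-class]
#'   (default [defaultRangeTable()]).
#' @param outDir output directory for artifacts; `NULL` to skip writing.
#' @param pThreshold edge significance threshold (default 0.05).
#' @param balanceTo named group sizes passed to [balanceGroups()], or `NULL`
#'   to balance both sexes down to the smaller group (the default), or
#'   `NA` to skip balancing.
#' @param nNetworks,subsampleSize ensemble protocol (defaults 30 and 60).
#' @param swReplicates Erdos-Renyi replicates in every small-world null.
#' @param seed master seed for every stochastic stage.
#' @return named list of all in-memory results (`cohorts`, `networks`,
#'   `topology`, `partitions`, `clusterNetworks`, `hierarchy`, `attacks`,
#'   `differential`, `pairedCentrality`, `hierarchyCorrelation`,
#'   `degreeKS`, `ensembles`, `ensembleComparison`, `exclusions`,
#'   `manifest`).
#' @export
runFullPipeline <- function(cohort, rangeTable = defaultRangeTable(),
                            outDir = NULL, pThreshold = 0.05,
                            balanceTo = NULL, nNetworks = 30L,
                            subsampleSize = 60L, swReplicates = 100L,
                            seed = 1L) {
  if (is.character(cohort)) cohort <- readCohortCSV(cohort)
  stopifnot(is(cohort, "PhysioCohort"))
  seed <- as.integer(seed)

  norm <- normalizeCohort(cohort, rangeTable)
  filt <- filterHealthy(norm)
  healthy <- filt$cohort

  if (!is.null(balanceTo) && length(balanceTo) == 1 && is.na(balanceTo[1])) {
    balanced <- healthy
  } else {
    if (is.null(balanceTo)) {
      tab <- table(cohortSex(healthy))
      balanceTo <- setNames(rep(min(tab), length(tab)), names(tab))
    }
    balanced <- balanceGroups(healthy, balanceTo, seed = seed)
  }

  sexes <- sort(unique(cohortSex(balanced)))
  perSex <- setNames(lapply(sexes, function(s) {
    subsetSubjects(balanced, which(cohortSex(balanced) == s))
  }), sexes)

  networks <- list()
  topology <- list()
  partitions <- list()
  clusterNets <- list()
  hierarchy <- list()
  attacks <- list()
  strategies <- c("random", "degree", "betweenness", "cascading")
  for (s in sexes) {
    net <- cohortNetwork(perSex[[s]], pThreshold = pThreshold)
    part <- louvainPartition(net, seed = seed)
    networks[[s]] <- net
    partitions[[s]] <- part
    topology[[s]] <- topologySummary(net, partition = part,
                                     swReplicates = swReplicates, seed = seed)
    clusterNets[[s]] <- contractClusters(net, part)
    hierarchy[[s]] <- hierarchyLayers(net)
    attacks[[s]] <- setNames(lapply(strategies, function(st) {
      attackNetwork(net, strategy = st, seed = seed)
    }), strategies)
  }

  cross <- list()
  if (length(sexes) == 2) {
    a <- sexes[1]
    b <- sexes[2]
    cross$differential <- differentialNetwork(networks[[a]], networks[[b]])
    cross$differential$labels <- c(a = a, b = b)
    cross$pairedCentrality <- pairedCentralityTests(networks[[a]],
                                                    networks[[b]])
    cross$hierarchyCorrelation <- hierarchyCorrelation(networks[[a]],
                                                       networks[[b]])
    cross$degreeKS <- compareDegreeDistributions(networks[[a]], networks[[b]])
    fullPerSex <- setNames(lapply(sexes, function(s) {
      subsetSubjects(healthy, which(cohortSex(healthy) == s))
    }), sexes)
    cross$ensembles <- setNames(lapply(sexes, function(s) {
      subsampleNetworks(fullPerSex[[s]], nNetworks = nNetworks,
                        subsampleSize = subsampleSize, seed = seed,
                        pThreshold = pThreshold,
                        swReplicates = swReplicates, label = s)
    }), sexes)
    cross$ensembleComparison <- compareEnsembles(cross$ensembles[[a]],
                                                 cross$ensembles[[b]])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("physiograph")),
    seed = seed, p_threshold = pThreshold,
    n_input = nrow(cohortValues(cohort)),
    n_healthy = nrow(cohortValues(healthy)),
    n_excluded = length(unique(filt$exclusions$subject_id)),
    group_sizes = as.list(table(cohortSex(balanced))),
    n_networks = nNetworks, subsample_size = subsampleSize,
    sw_replicates = swReplicates)

  result <- c(list(cohorts = list(normalized = norm, healthy = healthy,
                                  balanced = balanced, perSex = perSex),
                   exclusions = filt$exclusions,
                   networks = networks, topology = topology,
                   partitions = partitions, clusterNetworks = clusterNets,
                   hierarchy = hierarchy, attacks = attacks,
                   manifest = manifest),
              cross)

  if (!is.null(outDir)) writePipelineArtifacts(result, outDir)
  result
}

# Write the standard artifact set under outDir.
writePipelineArtifacts <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeCohortCSV(result$cohorts$balanced,
                 file.path(outDir, "cohort_normalized.csv"))
  write.csv(result$exclusions, file.path(outDir, "exclusions.csv"),
            row.names = FALSE)
  for (s in names(result$networks)) {
    writeNetworkGraphML(result$networks[[s]],
                        file.path(outDir, sprintf("network_%s.graphml", s)))
    writeNetworkEdgeList(result$networks[[s]],
                         file.path(outDir, sprintf("edges_%s.tsv", s)))
    memb <- partitionMembership(result$partitions[[s]])
    write.table(data.frame(node = names(memb), cluster = memb),
                file.path(outDir, sprintf("partition_%s.tsv", s)),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(result$topology[[s]],
                         file.path(outDir, sprintf("topology_%s.json", s)),
                         auto_unbox = TRUE, digits = NA)
    lay <- result$hierarchy[[s]]$layers
    write.table(data.frame(node = names(lay), layer = lay),
                file.path(outDir, sprintf("hierarchy_%s.tsv", s)),
                sep = "\t", row.names = FALSE, quote = FALSE, na = "")
    for (st in names(result$attacks[[s]])) {
      cu <- result$attacks[[s]][[st]]
      write.table(data.frame(k = seq_along(cu$loss),
                             fraction = seq_along(cu$loss) / cu$n,
                             loss = cu$loss),
                  file.path(outDir, sprintf("attack_%s_%s.tsv", s, st)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(result$differential)) {
    write.csv(result$differential$edges,
              file.path(outDir, "differential_edges.csv"), row.names = FALSE)
    igraph::write_graph(result$differential$graph,
                        file.path(outDir, "differential.graphml"),
                        format = "graphml")
    write.csv(result$ensembleComparison,
              file.path(outDir, "ensemble_comparison.csv"), row.names = FALSE)
    write.csv(result$pairedCentrality,
              file.path(outDir, "paired_centrality.csv"), row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
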