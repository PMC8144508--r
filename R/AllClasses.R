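#' @import methods
#' @importFrom stats cor cov pnorm pt qnorm rnorm runif sd var wilcox.test
#'   ks.test t.test complete.cases p.adjust setNames median
#' @importFrom utils read.csv write.csv write.table combn
NULL

#' Clinical reference-range table
#'
#' Holds per-variable, per-sex normalization bounds (the Low/High columns of
#' clinical guidelines). Each row gives the reference interval of one biomarker
#' for one sex (`"M"`, `"F"`, or `"both"`). A value at the low bound normalizes
#' to 0 and a value at the high bound to 1; healthy subjects are expected to
#' lie inside \[0, 1\] after normalization.
#'
#' One-sided guideline entries (only a Low or only a High bound published) are
#' stored with `NA` for the missing bound; [normalizeCohort()] completes them
#' from the observed data extreme when `fallbackPolicy` is `"data_range"`.
#'
#' @slot ranges data.frame with columns `variable_id`, `sex`, `min`, `max`,
#'   `source`; `min < max` whenever both are present.
#' @slot fallbackPolicy either `"data_range"` (variables without a configured
#'   range are normalized by the observed healthy-candidate data range) or
#'   `"error"`.
#' @export
setClass("ClinicalRangeTable",
  representation(ranges = "data.frame", fallbackPolicy = "character"),
  prototype(fallbackPolicy = "data_range")
)

setValidity("ClinicalRangeTable", function(object) {
  r <- object@ranges
  need <- c("variable_id", "sex", "min", "max")
  if (!all(need %in% names(r))) {
    return(sprintf("ranges must have columns %s", paste(need, collapse = ", ")))
  }
  if (!object@fallbackPolicy %in% c("data_range", "error")) {
    return("fallbackPolicy must be 'data_range' or 'error'")
  }
  if (!all(r$sex %in% c("M", "F", "both"))) {
    return("sex must be one of 'M', 'F', 'both'")
  }
  bad <- !is.na(r$min) & !is.na(r$max) & r$max <= r$min
  if (any(bad)) {
    return(sprintf("degenerate range (max <= min) for: %s",
                   paste(r$variable_id[bad], collapse = ", ")))
  }
  if (anyDuplicated(paste(r$variable_id, r$sex))) {
    return("duplicated (variable_id, sex) entries")
  }
  TRUE
})

#' Cohort of subjects by physiological variables
#'
#' A subjects-by-variables numeric matrix with a per-subject sex label and a
#' flag recording whether values have been normalized to clinical ranges.
#' Missing measurements are `NA` and are tolerated throughout (downstream
#' correlations use pairwise deletion).
#'
#' @slot values numeric matrix, subjects in rows (rownames = subject ids),
#'   variables in columns (colnames = variable ids).
#' @slot sex character vector, one of `"M"`/`"F"` per subject.
#' @slot normalized logical flag; `TRUE` after [normalizeCohort()].
#' @export
setClass("PhysioCohort",
  representation(values = "matrix", sex = "character", normalized = "logical"),
  prototype(normalized = FALSE)
)

setValidity("PhysioCohort", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) > 0 && (is.null(rownames(v)) || anyDuplicated(rownames(v)))) {
    return("values must have unique subject-id rownames")
  }
  if (is.null(colnames(v))) return("values must have variable-id colnames")
  if (length(object@sex) != nrow(v)) {
    return("sex must have one entry per subject")
  }
  if (!all(object@sex %in% c("M", "F"))) return("sex labels must be 'M' or 'F'")
  if (length(object@normalized) != 1L) return("normalized must be a scalar flag")
  TRUE
})

#' Pairwise Spearman correlation matrix under pairwise deletion
#'
#' Symmetric matrices of Spearman rank correlations, two-sided p-values from
#' the Student t approximation on `n_eff - 2` degrees of freedom, and the
#' effective number of jointly observed pairs per entry. Entries with fewer
#' than `minPairs` joint observations are undefined (`NA`) and excluded from
#' network construction.
#'
#' @slot rho numeric matrix of correlations (diagonal 1).
#' @slot p numeric matrix of two-sided p-values (diagonal 0).
#' @slot n integer matrix of effective pair counts.
#' @slot minPairs minimum joint observations required to define an entry.
#' @export
setClass("CorrelationMatrix",
  representation(rho = "matrix", p = "matrix", n = "matrix",
                 minPairs = "integer")
)

setValidity("CorrelationMatrix", function(object) {
  d <- dim(object@rho)
  if (d[1] != d[2]) return("rho must be square")
  if (!identical(d, dim(object@p)) || !identical(d, dim(object@n))) {
    return("rho, p, n must share dimensions")
  }
  if (is.null(colnames(object@rho))) return("rho must carry variable names")
  ok <- is.na(object@rho) | (object@rho >= -1 - 1e-12 & object@rho <= 1 + 1e-12)
  if (!all(ok)) return("rho entries must lie in [-1, 1]")
  TRUE
})

#' Weighted undirected physiological network
#'
#' Wraps an undirected igraph whose vertices are physiological variables and
#' whose edges are the statistically significant Spearman correlations, with
#' edge weight equal to the squared correlation (rho^2, always positive) and
#' the sign of the original correlation kept as an edge attribute.
#'
#' @slot graph an igraph object; edge attributes `weight` (rho^2 in (0, 1\]),
#'   `sign` (+1/-1), `rho`, `p`, `n_eff`.
#' @slot pThreshold the significance threshold used to admit edges.
#' @export
setClass("PhysioNetwork",
  representation(graph = "ANY", pThreshold = "numeric")
)

setValidity("PhysioNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (any(igraph::which_loop(g))) return("graph must not contain self-loops")
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    if (is.null(w) || any(w <= 0) || any(w > 1 + 1e-12)) {
      return("edge weights must lie in (0, 1]")
    }
  }
  TRUE
})

#' RR-interval series
#'
#' An ordered sequence of interbeat (RR) intervals in milliseconds, with
#' optional subject metadata (sex, age group).
#'
#' @slot intervals numeric vector of positive intervals (ms), length >= 2.
#' @slot meta named list of subject metadata.
#' @export
setClass("RRSeries",
  representation(intervals = "numeric", meta = "list"),
  prototype(meta = list())
)

setValidity("RRSeries", function(object) {
  x <- object@intervals
  if (length(x) < 2L) return("need at least 2 intervals")
  if (any(!is.finite(x)) || any(x <= 0)) {
    return("intervals must be finite and positive")
  }
  TRUE
})

#' Node partition of a physiological network
#'
#' A community assignment: one integer cluster label per node, the method that
#' produced it, and the weighted Newman modularity of the partition on its
#' source network.
#'
#' @slot membership named integer vector, labels contiguous from 1.
#' @slot method `"louvain"`, `"spinglass"` or `"manual"`.
#' @slot modularity weighted modularity of the partition.
#' @export
setClass("Partition",
  representation(membership = "integer", method = "character",
                 modularity = "numeric")
)

setValidity("Partition", function(object) {
  m <- object@membership
  if (is.null(names(m))) return("membership must be named by node")
  if (length(m) == 0L) return("empty partition")
  labs <- sort(unique(m))
  if (!identical(labs, seq_along(labs))) {
    return("labels must be contiguous integers starting at 1")
  }
  if (!object@method %in% c("louvain", "spinglass", "manual")) {
    return("method must be louvain, spinglass or manual")
  }
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "ClinicalRangeTable", function(object) {
  cat(sprintf("ClinicalRangeTable: %d ranges (%d variables), fallback = %s\n",
              nrow(object@ranges), length(unique(object@ranges$variable_id)),
              object@fallbackPolicy))
})

setMethod("show", "PhysioCohort", function(object) {
  cat(sprintf("PhysioCohort: %d subjects (%d F, %d M) x %d variables%s\n",
              nrow(object@values), sum(object@sex == "F"),
              sum(object@sex == "M"), ncol(object@values),
              if (object@normalized) ", normalized" else ""))
  nmiss <- sum(is.na(object@values))
  if (nmiss > 0) cat(sprintf("  %d missing values\n", nmiss))
})

setMethod("show", "CorrelationMatrix", function(object) {
  p <- ncol(object@rho)
  cat(sprintf("CorrelationMatrix: %d variables, %d pairs (%d undefined)\n",
              p, p * (p - 1) / 2,
              sum(is.na(object@rho[upper.tri(object@rho)]))))
})

setMethod("show", "PhysioNetwork", function(object) {
  cat(sprintf("PhysioNetwork: %d nodes, %d edges (p < %g)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@pThreshold))
})

setMethod("show", "RRSeries", function(object) {
  cat(sprintf("RRSeries: %d intervals, mean %.1f ms\n",
              length(object@intervals), mean(object@intervals)))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition (%s): %d nodes in %d clusters, modularity %.3f\n",
              object@method, length(object@membership),
              max(object@membership), object@modularity))
})

# ---- accessors --------------------------------------------------------------

#' @describeIn PhysioCohort-accessors subjects-by-variables value matrix
#' @export
cohortValues <- function(x) {
  stopifnot(is(x, "PhysioCohort"))
  x@values
}

#' Accessors for PhysioCohort
#'
#' @param x a [PhysioCohort-class] object.
#' @name PhysioCohort-accessors
#' @aliases cohortValues cohortSex subjectIds variableIds isNormalized
NULL

#' @describeIn PhysioCohort-accessors per-subject sex labels
#' @export
cohortSex <- function(x) {
  stopifnot(is(x, "PhysioCohort"))
  x@sex
}

#' @describeIn PhysioCohort-accessors subject identifiers
#' @export
subjectIds <- function(x) {
  stopifnot(is(x, "PhysioCohort"))
  rownames(x@values)
}

#' @describeIn PhysioCohort-accessors variable identifiers
#' @export
variableIds <- function(x) {
  stopifnot(is(x, "PhysioCohort"))
  colnames(x@values)
}

#' @describeIn PhysioCohort-accessors TRUE once values are range-normalized
#' @export
isNormalized <- function(x) {
  stopifnot(is(x, "PhysioCohort"))
  x@normalized
}

#' Underlying igraph of a PhysioNetwork
#'
#' @param x a [PhysioNetwork-class] object.
#' @return the igraph object carried by `x`.
#' @export
networkGraph <- function(x) {
  stopifnot(is(x, "PhysioNetwork"))
  x@graph
}

#' Edge table of a PhysioNetwork
#'
#' @param x a [PhysioNetwork-class] object.
#' @return data.frame with columns `var_a`, `var_b`, `weight`, `sign`, `rho`,
#'   `p`, `n_eff`, one row per edge.
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "PhysioNetwork"))
  g <- x@graph
  if (igraph::ecount(g) == 0) {
    return(data.frame(var_a = character(), var_b = character(),
                      weight = numeric(), sign = numeric(), rho = numeric(),
                      p = numeric(), n_eff = integer()))
  }
  ends <- igraph::as_edgelist(g)
  data.frame(var_a = ends[, 1], var_b = ends[, 2],
             weight = igraph::E(g)$weight, sign = igraph::E(g)$sign,
             rho = igraph::E(g)$rho, p = igraph::E(g)$p,
             n_eff = igraph::E(g)$n_eff)
}

#' Cluster membership of a Partition
#'
#' @param x a [Partition-class] object.
#' @return named integer vector of cluster labels.
#' @export
partitionMembership <- function(x) {
  stopifnot(is(x, "Partition"))
  x@membership
}

#' RR intervals of an RRSeries
#'
#' @param x an [RRSeries-class] object.
#' @return numeric vector of intervals (ms).
#' @export
rrIntervals <- function(x) {
  stopifnot(is(x, "RRSeries"))
  x@intervals
}
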