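# Clinical-range normalization, the health filter and group balancing.

#' Construct a ClinicalRangeTable
#'
#' @param ranges data.frame with columns `variable_id`, `sex` (`"M"`, `"F"` or
#'   `"both"`), `min`, `max` and optionally `source`. `NA` in `min` or `max`
#'   marks a one-sided guideline range.
#' @param fallbackPolicy `"data_range"` (default) to normalize unconfigured
#'   variables or missing bounds by the observed data range of healthy
#'   candidates, or `"error"` to refuse.
#' @return a [ClinicalRangeTable-class].
#' @export
ClinicalRangeTable <- function(ranges, fallbackPolicy = c("data_range", "error")) {
  fallbackPolicy <- match.arg(fallbackPolicy)
  ranges <- as.data.frame(ranges)
  if (is.null(ranges$source)) ranges$source <- ""
  ranges$variable_id <- as.character(ranges$variable_id)
  ranges$sex <- as.character(ranges$sex)
  ranges$min <- as.numeric(ranges$min)
  ranges$max <- as.numeric(ranges$max)
  new("ClinicalRangeTable", ranges = ranges[, c("variable_id", "sex", "min",
                                                "max", "source")],
      fallbackPolicy = fallbackPolicy)
}

#' Read a range configuration from CSV
#'
#' Expects columns `variable_id`, `sex`, `min`, `max` and optionally `source`;
#' empty cells in `min`/`max` encode one-sided ranges.
#'
#' @param path CSV file path.
#' @inheritParams ClinicalRangeTable
#' @return a [ClinicalRangeTable-class].
#' @export
readRangeTable <- function(path, fallbackPolicy = c("data_range", "error")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ClinicalRangeTable(df, fallbackPolicy = match.arg(fallbackPolicy))
}

#' The clinical reference ranges shipped with the package
#'
#' Low/High reference bounds for the 62 physiological variables of the study
#' design (anthropometry, vital signs, bioimpedance, hematic biometry, blood
#' chemistry and derived indices), per sex, as published in clinical
#' guidelines. Variables for which guidelines publish only one bound (or none)
#' carry `NA` and fall back to the observed data range.
#'
#' @inheritParams ClinicalRangeTable
#' @return a [ClinicalRangeTable-class].
#' @export
defaultRangeTable <- function(fallbackPolicy = c("data_range", "error")) {
  path <- system.file("extdata", "clinical_ranges.csv", package = "physiograph",
                      mustWork = TRUE)
  readRangeTable(path, fallbackPolicy = match.arg(fallbackPolicy))
}

#' Construct a PhysioCohort
#'
#' @param values numeric subjects-by-variables matrix (or data.frame); rownames
#'   are subject ids, colnames variable ids.
#' @param sex character vector of `"M"`/`"F"` labels, one per subject.
#' @param normalized logical; `TRUE` only for already range-normalized values.
#' @return a [PhysioCohort-class].
#' @export
PhysioCohort <- function(values, sex, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  new("PhysioCohort", values = values, sex = as.character(sex),
      normalized = normalized)
}

#' Read a biomarker cohort CSV
#'
#' Expects a header row with `subject_id`, `sex` (`M`/`F`) and one column per
#' variable id; empty cells are missing values.
#'
#' @param path CSV file path.
#' @return a [PhysioCohort-class] (not normalized).
#' @export
readCohortCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("subject_id" %in% names(df), "sex" %in% names(df))
  ids <- as.character(df$subject_id)
  sex <- as.character(df$sex)
  vals <- as.matrix(df[, setdiff(names(df), c("subject_id", "sex")), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  PhysioCohort(vals, sex)
}

#' Write a cohort to CSV
#'
#' @param cohort a [PhysioCohort-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
  df <- data.frame(subject_id = subjectIds(cohort), sex = cohortSex(cohort),
                   cohortValues(cohort), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Resolve the (min, max) bounds used for one variable and one sex.
# Sex-specific entries take precedence over "both"; NULL if unconfigured.
resolveRange <- function(rangeTable, variable, sex) {
  r <- rangeTable@ranges
  hit <- r[r$variable_id == variable & r$sex == sex, , drop = FALSE]
  if (nrow(hit) == 0) {
    hit <- r[r$variable_id == variable & r$sex == "both", , drop = FALSE]
  }
  if (nrow(hit) == 0) return(NULL)
  list(min = hit$min[1], max = hit$max[1])
}

#' Normalize a single value to a clinical range
#'
#' Maps a raw measurement onto the unit interval of its reference range:
#' `(v - min) / (max - min)`. Values below the low bound map below 0 and
#' values above the high bound above 1, which is what the health filter keys
#' on. Missing input stays missing.
#'
#' @param v numeric value(s) in the variable's units.
#' @param min,max reference-range bounds; `max > min` required.
#' @return normalized value(s), dimensionless.
#' @export
#' @examples
#' normalizeValue(135, 90, 120)  # 1.5: above the systolic range
normalizeValue <- function(v, min, max) {
  if (!is.finite(min) || !is.finite(max) || max <= min) {
    stop("degenerate range: max must exceed min")
  }
  (v - min) / (max - min)
}

#' Invert a clinical-range normalization
#'
#' @inheritParams normalizeValue
#' @param x normalized value(s).
#' @return raw value(s) in the variable's units.
#' @export
denormalizeValue <- function(x, min, max) {
  if (!is.finite(min) || !is.finite(max) || max <= min) {
    stop("degenerate range: max must exceed min")
  }
  min + x * (max - min)
}

#' Normalize a cohort to clinical reference ranges
#'
#' Applies [normalizeValue()] column-wise using each subject's sex to resolve
#' the applicable range. Missing bounds and unconfigured variables follow the
#' table's fallback policy: with `"data_range"` the observed per-sex data
#' extreme among the cohort completes the interval (so the observed minimum
#' maps to 0 and/or the maximum to 1), with `"error"` they abort.
#'
#' @param cohort a raw [PhysioCohort-class].
#' @param rangeTable a [ClinicalRangeTable-class].
#' @return a normalized [PhysioCohort-class] of the same shape; missing values
#'   are preserved.
#' @export
normalizeCohort <- function(cohort, rangeTable) {
  stopifnot(is(cohort, "PhysioCohort"), is(rangeTable, "ClinicalRangeTable"))
  if (isNormalized(cohort)) return(cohort)
  vals <- cohortValues(cohort)
  sex <- cohortSex(cohort)
  out <- vals
  for (s in unique(sex)) {
    rows <- sex == s
    for (v in colnames(vals)) {
      rng <- resolveRange(rangeTable, v, s)
      lo <- if (is.null(rng)) NA_real_ else rng$min
      hi <- if (is.null(rng)) NA_real_ else rng$max
      col <- vals[rows, v]
      if (!is.finite(lo) || !is.finite(hi)) {
        if (rangeTable@fallbackPolicy == "error") {
          stop(sprintf("no complete range for variable '%s' (sex %s)", v, s))
        }
        obs <- range(col, na.rm = TRUE)
        if (!is.finite(lo)) lo <- obs[1]
        if (!is.finite(hi)) hi <- obs[2]
        if (hi <= lo) hi <- lo + 1  # constant column: map to 0
      }
      out[rows, v] <- normalizeValue(col, lo, hi)
    }
  }
  PhysioCohort(out, sex, normalized = TRUE)
}

#' Apply the health filter to a normalized cohort
#'
#' Subjects are retained only if every non-missing normalized value lies in
#' \[0, 1\]; any value above 1 or below 0 excludes the row. Missing values
#' never trigger exclusion. The exclusion report enumerates, per excluded
#' subject, each offending variable with its normalized value.
#'
#' @param cohort a normalized [PhysioCohort-class].
#' @return list with elements `cohort` (the retained subjects) and
#'   `exclusions` (data.frame `subject_id`, `variable_id`, `value`).
#' @export
filterHealthy <- function(cohort) {
  stopifnot(is(cohort, "PhysioCohort"))
  if (!isNormalized(cohort)) stop("cohort must be normalized first")
  vals <- cohortValues(cohort)
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  excluded <- rowSums(bad) > 0
  reports <- data.frame(subject_id = character(), variable_id = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  if (any(excluded)) {
    idx <- which(bad[excluded, , drop = FALSE], arr.ind = TRUE)
    reports <- data.frame(
      subject_id = rownames(vals)[which(excluded)][idx[, 1]],
      variable_id = colnames(vals)[idx[, 2]],
      value = vals[excluded, , drop = FALSE][idx],
      stringsAsFactors = FALSE)
    reports <- reports[order(reports$subject_id, reports$variable_id), ]
    rownames(reports) <- NULL
  }
  kept <- PhysioCohort(vals[!excluded, , drop = FALSE],
                       cohortSex(cohort)[!excluded], normalized = TRUE)
  list(cohort = kept, exclusions = reports)
}

#' Balance group sizes by random subsampling
#'
#' Draws, per sex, a uniform random subsample without replacement of the
#' requested size (subjects of a sex not listed in `groupSizes` are kept in
#' full). Reproducible for a fixed seed.
#'
#' @param cohort a [PhysioCohort-class].
#' @param groupSizes named integer vector, e.g. `c(F = 81, M = 81)`.
#' @param seed integer RNG seed.
#' @return the subsampled [PhysioCohort-class].
#' @export
balanceGroups <- function(cohort, groupSizes, seed) {
  stopifnot(is(cohort, "PhysioCohort"))
  sex <- cohortSex(cohort)
  keep <- rep(TRUE, length(sex))
  set.seed(as.integer(seed))
  for (s in names(groupSizes)) {
    avail <- which(sex == s)
    k <- as.integer(groupSizes[[s]])
    if (k > length(avail)) {
      stop(sprintf("requested %d subjects of sex %s but only %d available",
                   k, s, length(avail)))
    }
    drop <- setdiff(avail, sort(sample(avail, k)))
    keep[drop] <- FALSE
  }
  PhysioCohort(cohortValues(cohort)[keep, , drop = FALSE], sex[keep],
               normalized = isNormalized(cohort))
}

#' Select a subset of subjects
#'
#' @param cohort a [PhysioCohort-class].
#' @param subjects subject ids or row indices.
#' @return the restricted [PhysioCohort-class].
#' @export
subsetSubjects <- function(cohort, subjects) {
  stopifnot(is(cohort, "PhysioCohort"))
  vals <- cohortValues(cohort)
  if (is.character(subjects)) subjects <- match(subjects, rownames(vals))
  PhysioCohort(vals[subjects, , drop = FALSE], cohortSex(cohort)[subjects],
               normalized = isNormalized(cohort))
}
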