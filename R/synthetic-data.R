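# Gaussian-copula cohort generator and AR(1) RR-series generator. These
# define the study conditions used for validation: every planted quantity
# (block membership, latent correlations, outliers, AR parameters) has a
# closed-form or bookkeeping ground truth the pipeline can be checked
# against.

#' Specification of a synthetic cohort
#'
#' The generator draws, per sex, a latent multivariate Gaussian with a
#' block-structured correlation matrix (constant correlation within each
#' variable block, constant between blocks), pushes each margin through the
#' Gaussian CDF, and maps the resulting uniform onto the interior of the
#' variable's clinical range (variables without a configured range stay on
#' the unit interval and are normalized by the data-range fallback
#' downstream). Because the map is strictly monotone, the Spearman
#' correlation of any generated pair equals the Gaussian-copula value
#' `(6 / pi) asin(rho_latent / 2)` regardless of margins.
#'
#' A fraction `outlierRate` of subjects gets one randomly chosen two-sided
#' variable pushed outside its clinical range (these subjects are the planted
#' "unhealthy" rows the health filter must find); a fraction `missingRate` of
#' the remaining cells is masked at random.
#'
#' @param nSubjects named vector, subjects per sex, e.g. `c(M = 81, F = 117)`.
#' @param blocks data.frame `variable_id`, `block` shared by both sexes.
#' @param withinRho,betweenRho named numeric per sex (or scalars): latent
#'   correlation within blocks and baseline between blocks.
#' @param coupling optional named list per sex of data.frames `block_a`,
#'   `block_b`, `rho`: specific inter-block couplings whose latent
#'   correlation replaces the baseline (how physiological subsystems are
#'   cross-linked differs between the sexes).
#' @param missingRate fraction of cells masked as missing.
#' @param outlierRate fraction of subjects planted with an out-of-range value.
#' @param seed integer RNG seed.
#' @return a `cohortSpec` list.
#' @export
cohortSpec <- function(nSubjects = c(M = 81, F = 117),
                       blocks,
                       withinRho = c(M = 0.5, F = 0.5),
                       betweenRho = c(M = 0.02, F = 0.02),
                       coupling = NULL,
                       missingRate = 0.02,
                       outlierRate = 0,
                       seed = 1L) {
  scal <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      setNames(rep(x, length(nSubjects)), names(nSubjects))
    } else x
  }
  stopifnot(missingRate >= 0, missingRate < 1,
            outlierRate >= 0, outlierRate < 1)
  structure(list(nSubjects = nSubjects, blocks = blocks,
                 withinRho = scal(withinRho), betweenRho = scal(betweenRho),
                 coupling = coupling,
                 missingRate = missingRate, outlierRate = outlierRate,
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

#' The shipped paper-like cohort specification
#'
#' 62 physiological variables in 9 blocks named after the functional clusters
#' of the study system (anthropometry, blood pressure, red cell, white cell,
#' lipid/glucose, nitrogen balance, bilirubin/uric acid, temperature,
#' bioimpedance), with 81 men and 117 women. Both sexes share tight
#' within-block correlation and a strong anthropometry-bioimpedance axis;
#' they differ in how subsystems are cross-linked: the male structure is
#' sparser and more modular (4 extra coupled block pairs, weak diffuse
#' background), the female one more densely cross-coupled (8 extra coupled
#' pairs and a higher diffuse background), emulating the qualitative sex
#' contrast the analysis is designed to detect: a denser, more connected,
#' more clustered female network and a sparser, more modular, more
#' small-world male network.
#'
#' @param seed integer RNG seed stored in the spec.
#' @param missingRate fraction of cells masked as missing (default 0.02).
#' @param outlierRate planted out-of-range subject fraction (default 0:
#'   the cohorts emulate already-screened healthy groups).
#' @return a `cohortSpec`.
#' @export
paperLikeSpec <- function(seed = 1L, missingRate = 0.02, outlierRate = 0) {
  blocks <- data.frame(
    variable_id = c(
      "B0", "B1", "DB1", "B2", "B3", "B4", "DB2", "DB3", "B6",
      "P0", "P1", "DP0", "DP1",
      "H7", "H8", "H9", "H10", "H11", "H12", "H13", "H14",
      "H0", "H1", "DH1", "H2", "H3", "DH2", "H4", "DH3", "H5",
      "M1", "M2", "M3", "M4", "M5", "M6", "M12", "DM0", "DM2",
      "M7", "M8", "M10", "DM1", "DM4", "DM3",
      "M9", "M19", "M20", "M21", "M22", "M13", "M17",
      "T0", "T1", "T2",
      "B7", "B8", "B9", "B10", "B11", "DB4", "DB5"),
    block = rep(c("anthropometry", "blood_pressure", "red_cell", "white_cell",
                  "lipid_glucose", "nitrogen", "bilirubin_uric",
                  "temperature", "bioimpedance"),
                times = c(9, 4, 8, 9, 9, 6, 7, 3, 7)))
  cp <- function(a, b, r) data.frame(block_a = a, block_b = b, rho = r)
  couplingM <- rbind(
    cp("anthropometry", "bioimpedance", 0.35),
    cp("blood_pressure", "red_cell", 0.30))
  couplingF <- rbind(
    cp("anthropometry", "bioimpedance", 0.45),
    cp("anthropometry", "red_cell", 0.45),
    cp("anthropometry", "blood_pressure", 0.45),
    cp("white_cell", "bilirubin_uric", 0.45),
    cp("white_cell", "lipid_glucose", 0.45),
    cp("white_cell", "bioimpedance", 0.45),
    cp("lipid_glucose", "bilirubin_uric", 0.45),
    cp("nitrogen", "lipid_glucose", 0.45),
    cp("red_cell", "bioimpedance", 0.45))
  withinM <- c(anthropometry = 0.42, blood_pressure = 0.42, red_cell = 0.42,
               white_cell = 0.35, lipid_glucose = 0.38, nitrogen = 0.38,
               bilirubin_uric = 0.30, temperature = 0.18, bioimpedance = 0.42)
  cohortSpec(nSubjects = c(M = 81, F = 117), blocks = blocks,
             withinRho = list(M = withinM, F = 0.50),
             betweenRho = c(M = 0.0, F = 0.12),
             coupling = list(M = couplingM, F = couplingF),
             missingRate = missingRate, outlierRate = outlierRate,
             seed = seed)
}

# Block-structured latent correlation matrix with optional specific
# inter-block couplings; repaired to the nearest PSD correlation matrix if
# the requested targets are not PSD.
blockCorrelation <- function(membership, within, between, coupling = NULL) {
  p <- length(membership)
  same <- outer(membership, membership, "==")
  S <- matrix(between, p, p)
  if (!is.null(coupling)) {
    for (i in seq_len(nrow(coupling))) {
      ia <- membership == coupling$block_a[i]
      ib <- membership == coupling$block_b[i]
      S[ia, ib] <- coupling$rho[i]
      S[ib, ia] <- coupling$rho[i]
    }
  }
  # `within` may be a scalar or a named vector of per-block values
  if (length(within) == 1L && is.null(names(within))) {
    S[same] <- within
  } else {
    for (bl in unique(membership)) {
      ib <- membership == bl
      w <- if (bl %in% names(within)) within[[bl]] else within[[1]]
      S[ib, ib] <- w
    }
  }
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    S <- as.matrix(Matrix::nearPD(S, corr = TRUE)$mat)
  }
  S
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohortSpec()].
#' @param rangeTable a [ClinicalRangeTable-class] giving the value ranges the
#'   copula margins are mapped into (default [defaultRangeTable()]).
#' @return a raw (un-normalized) [PhysioCohort-class]. Attributes record the
#'   ground truth: `blocks` (variable block membership) and `outliers`
#'   (planted out-of-range subject ids).
#' @export
generateCohort <- function(spec, rangeTable = defaultRangeTable()) {
  stopifnot(inherits(spec, "cohortSpec"))
  blocks <- spec$blocks
  vars <- as.character(blocks$variable_id)
  memb <- as.character(blocks$block)
  p <- length(vars)
  set.seed(spec$seed)
  allVals <- list()
  allSex <- character(0)
  outliers <- character(0)
  for (s in names(spec$nSubjects)) {
    n <- spec$nSubjects[[s]]
    S <- blockCorrelation(memb, spec$withinRho[[s]], spec$betweenRho[[s]],
                          spec$coupling[[s]])
    z <- matrix(rnorm(n * p), n, p) %*% chol(S)
    u <- pnorm(z)
    vals <- matrix(NA_real_, n, p, dimnames = list(NULL, vars))
    twoSided <- logical(p)
    for (j in seq_len(p)) {
      rng <- resolveRange(rangeTable, vars[j], s)
      lo <- if (is.null(rng)) NA_real_ else rng$min
      hi <- if (is.null(rng)) NA_real_ else rng$max
      twoSided[j] <- is.finite(lo) && is.finite(hi)
      # complete one-sided or absent guideline ranges with a plausible span
      # so generated healthy values always respect any configured bound
      if (!is.finite(lo) && !is.finite(hi)) {
        lo <- 0
        hi <- 1
      } else if (!is.finite(hi)) {
        hi <- lo + max(abs(lo) * 0.25, 1)
      } else if (!is.finite(lo)) {
        lo <- hi - max(abs(hi) * 0.25, 1)
      }
      # keep healthy draws strictly inside the interval
      vals[, j] <- lo + (0.02 + 0.96 * u[, j]) * (hi - lo)
    }
    ids <- sprintf("%s%03d", s, seq_len(n))
    rownames(vals) <- ids
    if (spec$outlierRate > 0 && any(twoSided)) {
      nOut <- round(spec$outlierRate * n)
      if (nOut > 0) {
        who <- sort(sample(n, nOut))
        for (i in who) {
          j <- sample(which(twoSided), 1)
          rng <- resolveRange(rangeTable, vars[j], s)
          span <- rng$max - rng$min
          vals[i, j] <- if (runif(1) < 0.5) {
            rng$min - runif(1, 0.05, 0.5) * span
          } else {
            rng$max + runif(1, 0.05, 0.5) * span
          }
        }
        outliers <- c(outliers, ids[who])
      }
    }
    if (spec$missingRate > 0) {
      mask <- matrix(runif(n * p) < spec$missingRate, n, p)
      # planted outlier cells stay observed so the filter can see them
      if (length(outliers)) mask[rownames(vals) %in% outliers, ] <- FALSE
      vals[mask] <- NA_real_
    }
    allVals[[s]] <- vals
    allSex <- c(allSex, rep(s, n))
  }
  cohort <- PhysioCohort(do.call(rbind, allVals), allSex)
  attr(cohort, "blocks") <- setNames(memb, vars)
  attr(cohort, "outliers") <- outliers
  cohort
}

#' Specification of a synthetic RR series
#'
#' @param nBeats number of intervals.
#' @param meanRR stationary mean (ms).
#' @param sdRR stationary standard deviation (ms).
#' @param phi lag-1 autocorrelation, |phi| < 1.
#' @param seed integer RNG seed.
#' @return an `rrSpec` list.
#' @export
rrSpec <- function(nBeats = 7200L, meanRR = 800, sdRR = 50, phi = 0.6,
                   seed = 1L) {
  stopifnot(abs(phi) < 1, sdRR >= 0, nBeats >= 2)
  structure(list(nBeats = as.integer(nBeats), meanRR = meanRR, sdRR = sdRR,
                 phi = phi, seed = as.integer(seed)),
            class = "rrSpec")
}

#' Generate a stationary AR(1) RR-interval series
#'
#' `rr_t = mean + phi (rr_(t-1) - mean) + eps_t` with
#' `eps_t ~ N(0, sd^2 (1 - phi^2))`, initialized from the stationary
#' distribution, so the series has stationary mean `meanRR`, variance
#' `sdRR^2` and lag-1 autocorrelation `phi`. In Poincare terms its limits are
#' `SD1^2 = sd^2 (1 - phi)` and `SD2^2 = sd^2 (1 + phi)`.
#'
#' @param spec an [rrSpec()].
#' @return an [RRSeries-class].
#' @export
generateRR <- function(spec) {
  stopifnot(inherits(spec, "rrSpec"))
  set.seed(spec$seed)
  n <- spec$nBeats
  x <- numeric(n)
  x[1] <- rnorm(1, 0, spec$sdRR)
  innovSD <- spec$sdRR * sqrt(1 - spec$phi^2)
  eps <- rnorm(n - 1, 0, innovSD)
  for (t in 2:n) x[t] <- spec$phi * x[t - 1] + eps[t - 1]
  RRSeries(spec$meanRR + x, meta = list(spec = spec))
}
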