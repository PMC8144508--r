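# RR-interval (heart rate variability) characterization: statistical moments,
# the momentum-space alpha radius, Shannon entropy and Poincare geometry.

#' Construct an RRSeries
#'
#' @param intervals numeric vector of positive RR intervals (ms).
#' @param meta optional named list of subject metadata (e.g. sex, age group).
#' @return an [RRSeries-class].
#' @export
RRSeries <- function(intervals, meta = list()) {
  new("RRSeries", intervals = as.numeric(intervals), meta = meta)
}

#' Read an RR-interval file
#'
#' Plain text, one interval (ms) per line; lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @param meta optional metadata list.
#' @return an [RRSeries-class].
#' @export
readRRFile <- function(path, meta = list()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  RRSeries(as.numeric(lines), meta = meta)
}

# Population central moment of order p.
centralMoment <- function(x, p) mean((x - mean(x))^p)

#' Statistical moments and the alpha radius of an RR series
#'
#' Computes the arithmetic mean, standard deviation, skewness and excess
#' kurtosis of the interval distribution, plus the momentum-space radius
#' `alpha = sqrt((SD/mu)^2 + sk^2 + k^2)` that measures deviation from a
#' Gaussian distribution (for which sk = k = 0, hence alpha = SD/mu). Smaller
#' alpha indicates a more rigid, less variable signal.
#'
#' Estimators are the uncorrected population moments: `SD = sqrt(m2)`,
#' `sk = m3 / m2^1.5`, `k = m4 / m2^2 - 3` (excess, Gaussian -> 0). A
#' constant series reports sd = sk = k = alpha = 0 by convention.
#'
#' @param rr an [RRSeries-class] (or numeric vector) of length >= 4.
#' @return named list: `mu`, `sd` (ms), `sk`, `k`, `alpha` (dimensionless).
#' @export
momentSummary <- function(rr) {
  x <- if (is(rr, "RRSeries")) rrIntervals(rr) else as.numeric(rr)
  if (length(x) < 4L) stop("need at least 4 intervals for kurtosis")
  mu <- mean(x)
  m2 <- centralMoment(x, 2)
  s <- sqrt(m2)
  if (s == 0) {
    return(list(mu = mu, sd = 0, sk = 0, k = 0, alpha = 0))
  }
  sk <- centralMoment(x, 3) / m2^1.5
  k <- centralMoment(x, 4) / m2^2 - 3
  list(mu = mu, sd = s, sk = sk, k = k,
       alpha = alphaRadius(mu = mu, sd = s, sk = sk, k = k))
}

#' Momentum-space alpha radius
#'
#' `alpha = sqrt((SD/mu)^2 + sk^2 + k^2)`, the Euclidean radius in the
#' coefficient-of-variation / skewness / excess-kurtosis space. A Gaussian
#' variable has sk = k = 0 so alpha reduces to SD/mu; shrinkage of any
#' coordinate's magnitude shrinks alpha (increased rigidity).
#'
#' @param mu mean (must be non-zero).
#' @param sd standard deviation.
#' @param sk skewness.
#' @param k excess kurtosis.
#' @return alpha, dimensionless.
#' @export
alphaRadius <- function(mu, sd, sk, k) {
  if (mu == 0) stop("alpha is undefined for mu = 0")
  sqrt((sd / mu)^2 + sk^2 + k^2)
}

#' Shannon entropy of the interval histogram
#'
#' Entropy (bits) of the equal-width histogram of the intervals over their
#' observed range: `-sum p log2 p` with `0 log 0 = 0`. Bounded by
#' `log2(nBins)`; a constant signal has zero entropy.
#'
#' @param rr an [RRSeries-class] or numeric vector.
#' @param nBins number of equal-width bins (default 16).
#' @return entropy in bits.
#' @export
shannonEntropy <- function(rr, nBins = 16L) {
  x <- if (is(rr, "RRSeries")) rrIntervals(rr) else as.numeric(rr)
  stopifnot(nBins >= 1L, length(x) >= 1L)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = nBins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Poincare-plot ellipse geometry
#'
#' From the lag-1 scatter of the series (RR\[i+1\] against RR\[i\]):
#' `SD1 = sqrt(Var(diff(RR)) / 2)` is the dispersion perpendicular to the
#' identity line and `SD2 = sqrt(2 Var(RR) - SD1^2)` along it, with the
#' population variance convention, so that `SD1^2 + SD2^2 = 2 Var(RR)` holds
#' exactly. Eccentricity is that of the (SD1, SD2) ellipse:
#' `sqrt(1 - (min/max)^2)`, 0 iff SD1 = SD2.
#'
#' For a stationary AR(1) series with variance `s2` and lag-1 autocorrelation
#' `phi`, `SD1^2 -> s2 (1 - phi)` and `SD2^2 -> s2 (1 + phi)`; white noise
#' (`phi = 0`) gives a circular cloud.
#'
#' @param rr an [RRSeries-class] or numeric vector of length >= 3.
#' @return named list: `sd1`, `sd2` (ms), `eccentricity` in \[0, 1\],
#'   `clamped` (TRUE if `2 Var - SD1^2` was clamped to 0).
#' @export
poincareSummary <- function(rr) {
  x <- if (is(rr, "RRSeries")) rrIntervals(rr) else as.numeric(rr)
  if (length(x) < 3L) stop("need at least 3 intervals")
  d <- diff(x)
  popvar <- function(z) mean((z - mean(z))^2)
  sd1 <- sqrt(popvar(d) / 2)
  sd2sq <- 2 * popvar(x) - sd1^2
  clamped <- sd2sq < 0
  sd2 <- sqrt(max(sd2sq, 0))
  ecc <- if (sd1 == 0 && sd2 == 0) {
    0
  } else {
    ax <- sort(c(sd1, sd2))
    sqrt(1 - (ax[1] / ax[2])^2)
  }
  list(sd1 = sd1, sd2 = sd2, eccentricity = ecc, clamped = clamped)
}

#' Full HRV summary of an RR series
#'
#' Convenience wrapper combining [momentSummary()], [shannonEntropy()] and
#' [poincareSummary()].
#'
#' @inheritParams shannonEntropy
#' @return named list of all summary fields.
#' @export
hrvSummary <- function(rr, nBins = 16L) {
  c(momentSummary(rr),
    list(entropy = shannonEntropy(rr, nBins)),
    poincareSummary(rr)[c("sd1", "sd2", "eccentricity")])
}

#' Compare HRV summaries between groups with Student's t test
#'
#' Runs a two-sided two-sample t test of every group against a designated
#' reference group, for every numeric summary field.
#'
#' @param groups named list; each element is a list/data.frame of per-subject
#'   summaries (as returned by [hrvSummary()]) for one group.
#' @param reference name of the reference group.
#' @param varEqual logical, passed to [stats::t.test()] (default TRUE:
#'   classical Student's t).
#' @return data.frame with columns `group`, `metric`, `t`, `p`,
#'   `mean_group`, `mean_reference`.
#' @export
compareGroupsT <- function(groups, reference, varEqual = TRUE) {
  if (!reference %in% names(groups)) {
    stop(sprintf("reference group '%s' not found", reference))
  }
  toMat <- function(g) {
    do.call(rbind, lapply(g, function(s) unlist(s[vapply(s, is.numeric, TRUE)])))
  }
  ref <- toMat(groups[[reference]])
  out <- list()
  for (gname in setdiff(names(groups), reference)) {
    gm <- toMat(groups[[gname]])
    for (metric in intersect(colnames(ref), colnames(gm))) {
      a <- gm[, metric]
      b <- ref[, metric]
      if (length(a) < 2 || length(b) < 2) next
      if (sd(a) == 0 && sd(b) == 0) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- t.test(a, b, var.equal = varEqual)
      }
      out[[length(out) + 1L]] <- data.frame(
        group = gname, metric = metric,
        t = unname(tt$statistic), p = tt$p.value,
        mean_group = mean(a), mean_reference = mean(b))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
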