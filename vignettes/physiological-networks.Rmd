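---
title: "Clinical-range-normalized physiological networks and HRV summaries: methods"
author: "physiograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical-range-normalized physiological networks and HRV summaries: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package computes

`physiograph` studies sex differences in physiological regulation through two
complementary lenses:

1. **Time series**: RR (interbeat) interval series are summarized by their
   statistical moments, a momentum-space deviation-from-Gaussian radius,
   Shannon entropy and the Poincaré ellipse, then compared between groups.
2. **Cross-sectional networks**: a subjects-by-biomarkers table (anthropometry,
   vital signs, bioimpedance, hematic biometry, blood chemistry, derived
   indices) is normalized against clinical reference ranges, screened for
   health, and turned into a weighted undirected correlation network per sex.
   Networks are compared by topology, community structure, node hierarchy,
   differential edges and resilience to simulated attacks.

A Gaussian-copula synthetic-cohort generator and an AR(1) RR-series generator
supply ground truth for every stage; they are first-class, tested components,
not test scaffolding.

# Clinical-range normalization and the health filter

Each biomarker value $V$ is mapped onto its sex-specific clinical reference
interval $[\mathrm{Min}, \mathrm{Max}]$:

$$X = \frac{V - \mathrm{Min}}{\mathrm{Max} - \mathrm{Min}}$$

so 0 and 1 are the guideline bounds, not data quantiles. This makes
out-of-range values immediately visible: a subject is retained as *healthy*
only if every non-missing normalized value lies in $[0, 1]$. Missing values
never trigger exclusion — downstream correlations use pairwise deletion, so
missingness is tolerated throughout.

Design choices worth spelling out:

* **One-sided guideline ranges.** Some variables publish only a Low or only a
  High bound (e.g. height, waist-to-hip ratio). The exclusion rule needs both
  bounds, so the missing side is completed by the observed data extreme among
  the cohort (`fallbackPolicy = "data_range"`); the observed minimum maps to 0
  (or maximum to 1) exactly, which is inside the healthy interval. Variables
  with no published range at all are normalized entirely by the data range.
* **Precedence.** A sex-specific range beats a `both` entry; `both` is only a
  fallback.
* **Group balancing.** When group sizes differ, `balanceGroups()` draws a
  uniform subsample without replacement per sex (a single seed recorded in the
  pipeline manifest), so the two networks are estimated from equally many
  subjects and edge counts are comparable.

The shipped range table (`inst/extdata/clinical_ranges.csv`,
`defaultRangeTable()`) is an editable CSV keyed by `(variable_id, sex)` with a
free-text `source` column for the guideline citation.

# HRV summaries

For a series of $n$ intervals we use uncorrected population central moments
$m_p = \frac{1}{n}\sum (x_i - \bar x)^p$: $\mathrm{SD} = \sqrt{m_2}$, skewness
$sk = m_3 / m_2^{3/2}$ and **excess** kurtosis $k = m_4 / m_2^2 - 3$. The
momentum-space radius

$$\alpha = \sqrt{(\mathrm{SD}/\mu)^2 + sk^2 + k^2}$$

measures deviation from Gaussian behaviour; for a Gaussian variable
$sk = k = 0$, so $\alpha = \mathrm{SD}/\mu$, and shrinkage of any coordinate's
magnitude (less dispersion, more symmetry, less leptokurtosis) shrinks
$\alpha$ — increased rigidity of the signal. The excess-kurtosis convention is
what makes the Gaussian identity hold; with Pearson kurtosis it would not.
A constant series reports $sk = k = \alpha = 0$ rather than NaN.

The Poincaré plot (the lag-1 scatter $RR_{i+1}$ vs $RR_i$) is summarized by
the dispersion perpendicular to and along the identity line:

$$\mathrm{SD1}^2 = \tfrac{1}{2}\operatorname{Var}(\Delta RR), \qquad
  \mathrm{SD2}^2 = 2\operatorname{Var}(RR) - \mathrm{SD1}^2,$$

with the same population variance convention, so
$\mathrm{SD1}^2 + \mathrm{SD2}^2 = 2\operatorname{Var}(RR)$ holds exactly —
the suite asserts it to $10^{-10}$. For a stationary AR(1) process with
variance $\sigma^2$ and lag-1 autocorrelation $\phi$,
$\mathrm{SD1}^2 \to \sigma^2(1-\phi)$ and
$\mathrm{SD2}^2 \to \sigma^2(1+\phi)$, which is the closed form the generator
tests recover. Note that conventions for which axis is "short-term" vary in
the applied literature; we therefore name the axes strictly by their formulas
above (SD1 across the identity line, SD2 along it). If numerical cancellation
ever drives $\mathrm{SD2}^2$ below zero it is clamped to 0 and flagged.

Shannon entropy is computed on the equal-width histogram of the intervals over
their observed range, in bits, with $0 \log 0 \equiv 0$; it is 0 for a
constant signal and at most $\log_2(\text{bins})$. Whether to bin values or
symbol sequences is a genuine modelling choice; the binned-value histogram
with a default of 16 bins is ours, and `nBins` is exposed because no single
value is canonical. Entropy is invariant to affine rescaling of the intervals
(the binning rescales with the range), which the suite also asserts.

Group contrasts use the classical two-sided two-sample Student t test of
every group against a designated reference group, per summary field.

# Correlation network construction

Pairwise association uses the Spearman rank correlation: for each unordered
pair of variables, ranks are computed on the jointly observed rows only
(pairwise deletion, no imputation), with midranks for ties, and

$$\rho = \frac{\operatorname{cov}(rk_X, rk_Y)}{SD_{rk_X}\, SD_{rk_Y}}.$$

Significance comes from the Student t approximation
$t = \rho\sqrt{(n_\mathrm{eff}-2)/(1-\rho^2)}$ on $n_\mathrm{eff}-2$ degrees
of freedom, two-sided; $|\rho| = 1$ maps to $p = 0$ rather than NaN. Entries
with fewer than `minPairs` (default 3) joint observations are undefined and
can never become edges. The t approximation on midranks is used as-is under
ties; no tie-specific correction is applied beyond midranking itself.

An edge joins two variables iff $p < 0.05$ (the threshold is a parameter);
its weight is $\rho^2$ — strictly positive, in $(0, 1]$ — and the sign of the
original $\rho$ is kept as an edge attribute. No multiple-testing correction
is applied by default, matching the single-threshold construction the
pipeline replicates; a Benjamini–Hochberg flag and a row-bootstrap
edge-stability filter (keep edges significant in at least a fraction $q$ of
$B$ subject resamples) are available but off by default, as robustness
options rather than defaults.

Useful invariants, all asserted in the suite: $\rho$ is invariant under
strictly monotone transforms of either margin; the edge set is monotone in
the p threshold; the network is invariant to subject-row permutation; on
tie-free samples of up to 8 subjects $\rho$ equals the exhaustive
$1 - 6\sum d_i^2 / (n(n^2-1))$ formula exactly.

# Topology battery

With edge weights being similarities (squared correlations), not costs, every
path-based quantity — characteristic path length, diameter, betweenness,
efficiency — is computed on the **unweighted** thresholded graph; integer
hop-count diameters are the intended reading. A weighted-path variant
(distance $= 1/w$) would conflate correlation strength with traversal cost
and is deliberately not the default.

* **Connectedness** (Krackhardt): fraction of node pairs joined by some path.
* **Density**: $m / \binom{n}{2}$.
* **Clustering**: mean local weighted clustering in the Onnela/Fagiolo form —
  geometric-mean triangle intensity with weights rescaled by the maximum
  weight; nodes of degree < 2 contribute 0. On unweighted graphs this reduces
  to the usual local clustering mean.
* **Modularity**: weighted Newman modularity of the Louvain partition of the
  same network (or a supplied partition).
* **Efficiency**: mean of $1/d(i,j)$ over distinct ordered pairs, unreachable
  pairs contributing 0 — so efficiency, like connectedness, absorbs the
  disconnection penalty, while CPL and diameter are reported on the largest
  component (finite even for partially disconnected networks).
* **Freeman betweenness centralization**: standard normalization; 1 exactly
  on a star.
* **Small-world index**: $(C/C_\mathrm{rand})/(L/L_\mathrm{rand})$ with the
  null being Erdős–Rényi $G(n, m)$ matched on node and edge count, averaged
  over $R = 100$ seeded replicates. The numerator uses mean local clustering
  (unweighted) on both the observed and null graphs, so numerator and null
  are commensurable; a transitivity-based numerator is available behind a
  flag. On an Erdős–Rényi graph the index is $\approx 1$, which the suite
  checks within Monte-Carlo error.

Eigencentrality is the leading eigenvector of the weighted adjacency,
computed by a dense symmetric eigendecomposition (deterministic — no random
restarts — and exact at these sizes, ~62 nodes), rescaled to maximum 1.
Betweenness is shortest-path betweenness on the unweighted graph; where the
applied literature sometimes substitutes flow betweenness, we use the
shortest-path variant throughout and note the alternative. Strength is the
sum of incident $\rho^2$.

Assortativity of a node attribute is the Pearson correlation of endpoint
values over the edge list with each edge counted in both orientations. It
carries the usual finite-size bias of order $-1/(n-1)$, visible in the null
tests.

# Hierarchy layers

The hierarchy roots at the node of maximal eigencentrality (ties broken by
strength, then id). Cycles are broken weakest-edge-first: repeatedly deleting
the weakest edge that still lies on a cycle is exactly the reverse-delete
algorithm, whose result is the maximum-weight spanning forest, so the
implementation computes that forest directly (tie behaviour among
equal-weight edges follows the spanning-tree routine; weights from continuous
data are ties-free in practice). Layers are BFS depths from the root within
the forest; nodes in other components are flagged unreachable rather than
given a layer — mirroring genuinely isolated variables in sparse networks.

# Communities and partition comparison

Louvain (weighted modularity optimization) and Spinglass (Potts-model
annealing, run per connected component, singleton clusters for isolated
nodes) both come from igraph, seeded for reproducibility; the partitions,
their modularity, and the comparison metrics are recomputed by this package
from the contingency table:

* variation of information $VI = H(A) + H(B) - 2I(A,B)$, reported in bits so
  the closed forms are clean (singletons-vs-one-block on 4 nodes gives
  exactly 2 bits);
* normalized mutual information $2I/(H(A)+H(B))$, defined as 1 when both
  partitions are trivial;
* Rand index from pair counts.

The igraph implementations of these metrics serve as an independent oracle in
the tests, never as the implementation. Cluster contraction collapses each
cluster onto its most eigencentral member (ties by strength), sums the
weights of all inter-cluster edges and drops intra-cluster ones, so total
inter-cluster weight is conserved — asserted in the suite. A utility orders
variables by the angle $\mathrm{atan2}(PC_2, PC_1)$ of their loadings on the
first two eigenvectors of the correlation matrix, for heatmap display.

# Attack resilience

Connectivity loss after removing a node set is
$1 - (\text{connected pairs in residual})/(\text{connected pairs intact})$ —
reachable-pair semantics. Strategies:

* `random`: uniform removal order, averaged over 100 seeded replicates;
* `degree`, `betweenness`: descending order of the metric computed once on
  the intact graph (a recomputed mode exists behind a flag);
* `cascading`: betweenness recomputed on the residual graph after every
  removal, removing the current maximum.

Ties everywhere break by strength, then id, making directed attacks fully
deterministic. `removalFractionForLoss()` reports the smallest removed
fraction whose loss reaches a target (e.g. 70%). A point worth noting when
reading attack curves: as long as the residual graph stays connected, the
loss after removing $k$ of $n$ nodes is $1 - \binom{n-k}{2}/\binom{n}{2}$
regardless of strategy, so 70% loss cannot occur before ~45% removal; small
removal fractions at 70% loss are a signature of fragmentation, which only
sparse modular networks exhibit.

The differential network classifies each edge of two networks over a shared
variable universe as `shared`, `a_only` or `b_only`; the three sets are
disjoint, their union is the union of the edge sets, and
`shared + a_only = |E_A|` (likewise for B) — all asserted.

# Cohort comparison protocol

To test topology differences statistically, 30 networks per group are built
from random 60-subject subsamples (without replacement within a replicate;
replicate seeds derived from the master seed by unit increments), each run
through the full correlation → threshold → topology chain, and each metric is
compared between groups by a two-sided Mann–Whitney test on the 30 replicate
values (normal approximation with tie correction at this size; exact when
samples are small and tie-free). Louvain is re-run per replicate since
modularity is partition-dependent. Node-level agreement between two networks
uses Wilcoxon matched-pairs signed-rank statistics in the signed-rank-sum
convention ($W = \sum \operatorname{sign}(d_i)\,\mathrm{rank}|d_i|$, 0 for
identical networks) and the Spearman correlation of paired centralities;
hierarchy agreement correlates layer depths over nodes reachable in both.

# The synthetic generator

Per sex, subjects are drawn from a latent multivariate Gaussian whose
correlation matrix has: a within-block value per variable block, specific
coupled block pairs with their own correlation, and a diffuse background for
all remaining pairs (non-PSD targets are repaired by nearest-PSD projection).
Margins go through the Gaussian CDF and an affine map into the interior of
each variable's clinical range (2%–98% of the interval), so generated healthy
subjects always pass the health filter and planted outliers — pushed
explicitly outside a two-sided range — are exactly the subjects the filter
must find. Because the margin map is strictly monotone, the Spearman
correlation of any pair has the Gaussian-copula closed form
$\rho_S = \frac{6}{\pi}\arcsin(\rho_\mathrm{latent}/2)$, which is what makes
analytic oracles possible for the whole pipeline.

The shipped `paperLikeSpec()` encodes the study conditions the analysis is
designed for: 62 variables in 9 physiological blocks (anthropometry, blood
pressure, red cell, white cell, lipid/glucose, nitrogen balance,
bilirubin/uric acid, temperature, bioimpedance), 81 men and 117 women, 2%
missingness. The sexes share tight block structure and a strong
anthropometry–bioimpedance axis but differ in cross-linking: the male
structure has two coupled block pairs, no diffuse background and a weakly
cohesive temperature block (so male networks sit in the sparse, modular,
occasionally disconnected regime), while the female structure has nine
coupled pairs and a diffuse background of 0.12 (denser, more clustered, more
uniformly connected). These values were fixed once, by calibrating to the
qualitative regime the method targets — sparse male networks that fragment
under targeted attack, denser female networks that resist — and verifying the
directional contrast across several independent seeds before any assertion
was written.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: skewed or heavy-tailed marginals (the copula margins
are smooth and symmetric before range mapping), deterministic
derived-variable identities (e.g. an index computed from two other columns),
structured missingness (assay batches), measurement error correlated across
variables, and any age structure. Spearman statistics are margin-free, so the
first limitation is immaterial for the correlation arm, but absolute values
of, say, attack fractions should be read as regime-level, not as predictions
of any particular cohort's numbers.

The RR generator is a stationary AR(1),
$x_t = \mu + \phi(x_{t-1} - \mu) + \varepsilon_t$,
$\varepsilon_t \sim N(0, \sigma^2(1-\phi^2))$, initialized from the
stationary law; defaults (7200 beats ≈ 2 h of recording at 800 ms, σ = 50 ms,
φ = 0.6) are in the physiological range for resting adults. It reproduces
mean, SD and φ (via SD1/SD2) within 3 Monte-Carlo standard errors at
$n = 10^4$ in the suite.

# Problem sizes and reproducibility

The full pipeline on the default spec — normalization, filtering, balancing,
two cohort networks, 60 subsampled networks with 100-replicate small-world
nulls each, partitions, hierarchies, four attack strategies per sex and all
cross-sex comparisons — runs in well under a minute on one CPU; the test
suite uses reduced replicate counts (5–30 small-world replicates, 8–10
subsample networks) chosen to keep each property detectable at its stated
tolerance while the whole suite stays in the tens of seconds. Every
stochastic stage takes an explicit seed, replicate seeds are derived from the
master seed by fixed increments, and the pipeline manifest records seeds,
thresholds and counts, so a rerun with the same inputs is numerically
identical.

# Known limitations

* The p < 0.05 edge rule without correction admits a floor of false edges
  (~5% of null pairs); with 62 variables that is ≈90 chance edges, which
  bounds how sparse a thresholded network can be. The BH and bootstrap
  filters exist for analyses where that floor matters.
* Spinglass is defined per connected component; cross-component community
  structure is not meaningful, and isolated nodes are singleton clusters by
  construction.
* The small-world null matches only $n$ and $m$; degree-sequence-preserving
  nulls are out of scope.
* Quantitative reproduction of any specific cohort's printed results
  requires that cohort's subject-level tables, which are not bundled; the
  corresponding check in the suite fails visibly (rather than skipping)
  until they are supplied under `inst/extdata/sm2/`.
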