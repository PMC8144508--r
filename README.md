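# physiograph

Sex differences in physiological regulation, studied two ways: heart-rate
variability (HRV) time-series summaries, and correlation networks built from
clinical-range-normalized biomarker tables.

## The problem

Physiological variables do not vary in isolation: blood pressure, red-cell
indices, anthropometry, metabolic and immune markers are coupled by
homeostatic regulation, and the *pattern* of coupling — not just the marginal
values — differs between healthy men and women. `physiograph` implements a
pipeline for quantifying that pattern:

1. **Normalization.** Each biomarker value `V` is mapped onto its sex-specific
   clinical reference interval: `X = (V − Min)/(Max − Min)`, so 0 and 1 are
   guideline bounds rather than data quantiles. Subjects with any normalized
   value outside [0, 1] are excluded as non-healthy (missing values are
   tolerated).
2. **Network construction.** For every variable pair, the Spearman rank
   correlation ρ is computed on jointly observed rows (pairwise deletion,
   midranks for ties) and tested with the Student t approximation on
   `n − 2` degrees of freedom. Pairs with `p < 0.05` become edges of an
   undirected network with weight ρ² (sign kept as an attribute).
3. **Comparison.** Networks are characterized by a topology battery
   (Krackhardt connectedness, density, weighted clustering, modularity,
   small-world index vs an Erdős–Rényi null, efficiency, path lengths,
   Freeman centralization), communities (Louvain, Spinglass; compared by
   variation of information, NMI, Rand index), eigencentrality hierarchies,
   a differential network (shared / group-exclusive edges), targeted-attack
   resilience curves (random, degree, betweenness, cascading), and a
   30×60-subsampling Mann–Whitney protocol for metric-wise group tests.

For HRV, RR-interval series are summarized by population moments, the
momentum-space radius `α = sqrt((SD/μ)² + sk² + k²)` (equal to SD/μ for a
Gaussian signal; smaller α = more rigid), histogram Shannon entropy, and the
Poincaré ellipse axes `SD1² = Var(ΔRR)/2`, `SD2² = 2·Var(RR) − SD1²`.

A Gaussian-copula synthetic-cohort generator (block-correlated latent
structure mapped into clinical ranges; Spearman ρ has the closed form
`(6/π)·asin(ρ_latent/2)`) and an AR(1) RR generator provide ground truth for
every stage. See the methods vignette
(`vignettes/physiological-networks.Rmd`) for the full model description.

## Worked example

```r
library(physiograph)

spec <- paperLikeSpec(seed = 42)        # 62 variables, 9 blocks, 81 M / 117 F
cohort <- generateCohort(spec)
cohort
#> PhysioCohort: 198 subjects (117 F, 81 M) x 62 variables
#>   251 missing values

res <- runFullPipeline(cohort, nNetworks = 30, subsampleSize = 60, seed = 42)
res$networks$M
#> PhysioNetwork: 62 nodes, 341 edges (p < 0.05)
res$networks$F
#> PhysioNetwork: 62 nodes, 875 edges (p < 0.05)
```

The male network is sparser and more modular; the female network denser and
more uniformly connected. The 30-replicate subsampling protocol makes that a
statistical statement (`mean_a` = women, `mean_b` = men here):

```r
cmp <- res$ensembleComparison
cmp[cmp$metric %in% c("density", "modularity", "small_world_index"), ]
#>              metric mean_a   sd_a mean_b    sd_b   U        p
#> 2           density  0.433 0.0299  0.164 0.00574 900 3.00e-11
#> 4        modularity  0.416 0.0269  0.530 0.03339   1 3.38e-17
#> 5 small_world_index  1.662 0.0973  2.649 0.15408   0 1.69e-17
```

Node roles stay correlated across the sexes even though the wiring differs,
and the sparser male network loses 70% of its pair connectivity under a
cascading (recomputed-betweenness) attack earlier than the female one:

```r
res$pairedCentrality[1, c("centrality", "spearman_rho")]
#>        centrality spearman_rho
#> 1 eigencentrality        0.613

100 * removalFractionForLoss(res$attacks$M$cascading, 0.7)  # 25.8 (% of nodes)
100 * removalFractionForLoss(res$attacks$F$cascading, 0.7)  # 29.0
```

HRV of a synthetic 2-hour AR(1) recording (φ = 0.6, σ = 50 ms):

```r
rr <- generateRR(rrSpec(nBeats = 7200, meanRR = 800, sdRR = 50, phi = 0.6,
                        seed = 42))
str(hrvSummary(rr))
#> $ mu     : num 799        # mean RR, ms
#> $ sd     : num 50.5
#> $ alpha  : num 0.0853     # ≈ SD/mu: near-Gaussian signal
#> $ entropy: num 3.09       # bits, of a 16-bin histogram
#> $ sd1    : num 31.7       # ≈ sqrt(50²·(1−φ)) = 31.6
#> $ sd2    : num 64         # ≈ sqrt(50²·(1+φ)) = 63.2
```

`SD1/SD2` recover the planted autocorrelation:
`φ̂ = (SD2² − SD1²)/(SD2² + SD1²) ≈ 0.6`.

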