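Package: physiograph
Title: Clinical-Range-Normalized Physiological Correlation Networks and
    Heart Rate Variability Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study sex differences in physiology from two
    complementary angles: characterization of RR-interval (heart rate
    variability) time series by statistical moments, a momentum-space
    deviation-from-Gaussian radius, Shannon entropy and Poincare ellipse
    geometry; and construction and comparison of physiological networks
    built from clinical-range-normalized biomarker tables via Spearman
    rank correlation with pairwise deletion, significance thresholding
    and squared-coefficient edge weights. Includes network topology
    batteries, community detection and partition comparison, hierarchy
    layering, targeted-attack resilience simulations, differential
    networks, a subsampled cohort-comparison protocol, and a
    Gaussian-copula synthetic cohort and AR(1) RR-series generator that
    provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
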