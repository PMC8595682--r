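Package: powersc
Title: Power Analysis and Experimental Design for Multi-Sample Single-Cell
    RNA-Seq Studies
Version: 0.1.0
Authors@R:
    person("powersc", "maintainers", email = "powersc@example.org",
           role = c("aut", "cre"))
Description: Analytic design of multi-sample single-cell RNA-seq experiments
    under a pseudobulk analysis. Fits cell-type-specific expression priors
    from pilot count data (per-gene negative-binomial parameters, a censored
    gamma-mixture over gene means, a mean-dispersion trend and read-depth
    saturation curves), computes the probability to detect rare cell types
    and the per-gene and overall power to detect differentially expressed
    genes and eQTL genes (negative-binomial two-rate tests, noncentral-F and
    count-level simulation, Bonferroni and FDR-inverted significance
    thresholds), and optimizes sample size, cells per sample and read depth
    under a fixed sequencing budget including droplet-overloading doublet
    adjustments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
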