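Package: paleoniche
Title: Presence-Only Niche Hindcasting, Range Dynamics and Canid Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct a montane endemic's bioclimatic niche through
    time from presence-only data: a from-scratch maximum-entropy
    (presence-background Gibbs) model with linear, quadratic, product, hinge
    and threshold features; ensembles of small models tuned by spatial-block
    cross-validation and weighted by AUC; variable pre-processing (standardized
    PCA, iterative VIF filtering, MESS transferability screening, block
    aggregation); minimum-useful-threshold range binarization with
    good-to-best/good-to-worst accounting, Brown-Forsythe variance comparison
    and ARIMA-error trend regression; FRAGSTATS-style landscape fragmentation
    metrics with permutational MANOVA scenario comparisons; and a morphometric
    classification suite (log-PCA, stepwise Wilks-lambda discriminant analysis,
    bootstrap cluster analysis with UPGMA). A synthetic-data module generates
    climate series with orbital-style cycles, nested range polygons and
    multispecies measurement tables so the full pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS,
    nnet,
    mgcv,
    vegan,
    permute
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
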