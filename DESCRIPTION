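Package: natrajectory
Title: Three-Group RNA-Seq Differential Expression and Expression-Trajectory
    Analysis for Tumor-Adjacent Tissue Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bulk RNA-seq studies that compare normal
    tissue (N), histologically normal tumor-adjacent tissue (NAT) and tumor (T)
    from the same organ.  Implements low-expression gene filtering,
    median-of-ratios size-factor normalization, covariate-adjusted
    negative-binomial Wald tests (with paired designs via patient blocking),
    Benjamini-Hochberg adjustment, label-permutation empirical p-values,
    fold-change/adjusted-p/permutation-p DEG calling with a sex-bias exclusion
    screen, classification of DEGs into six N-to-NAT-to-T expression
    trajectories, DEG set-overlap and biotype-composition summaries, and
    PCA/average-linkage hierarchical clustering of log-normalized expression.
    A negative-binomial count simulator with planted covariate and trajectory
    effects provides ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    ape,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
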