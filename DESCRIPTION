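Package: aflpscape
Title: Landscape Genetics of Dominant AFLP Markers Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of dominant (presence/absence) marker data
    such as AFLP bands sampled from hierarchically structured plant populations
    along environmental gradients. Implements allele-frequency estimation under
    Hardy-Weinberg dominance, within-population diversity (percent polymorphic
    loci, unbiased expected heterozygosity), Nei distances with UPGMA trees and
    locus bootstrap, analysis of molecular variance (AMOVA) with Phi statistics
    and permutation inference, linear mixed models on pairwise distance matrices
    with parametric-bootstrap likelihood-ratio tests, multiple regression on
    distance matrices with forward stepwise selection and partial Mantel tests,
    three candidate-locus scans (an FST-outlier envelope scan, a Bayesian
    locus-effect decomposition with q-values, and an environmental-association
    logistic scan), locus-phenotype correlation, a k-means clustering surrogate
    for assigning population clusters, and a seedable synthetic-data generator
    with full ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
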