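Package: assemblyNet
Title: Community Assembly, Stochasticity and Co-Occurrence Network Stability
    for Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the balance of stochastic and deterministic
    assembly processes in microbial communities and the stability of their
    co-occurrence networks. Implements the Sloan neutral community model fit
    to occupancy-abundance data with a 95% prediction envelope, abundance-
    weighted phylogenetic beta-diversity (betaMNTD) with tip-shuffle null
    models and the phylogenetic normalized stochasticity ratio (pNST),
    thresholded Spearman co-occurrence networks with topology metrics and
    per-sample subnetworks, robustness and vulnerability simulations,
    Zi-Pi keystone classification, the supporting diversity and permutation
    statistics (rarefaction, Shannon, Faith PD, Bray-Curtis, Wilcoxon/FDR,
    Kruskal-Wallis with Brunner-Munzel post hoc, PERMANOVA, ANOSIM, RDA),
    and individual-based synthetic community generators for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    ape,
    vegan,
    picante,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
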