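Package: reciprocross
Title: Reciprocal-Cross RNA-Seq Analysis of Heritable Expression Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 2x2 reciprocal-cross RNA-seq experiments that
    contrast offspring of captive-bred (hatchery) and natural-origin parents.
    Provides a crossing-design and count simulator with planted ancestry,
    maternal, paternal, sex, batch and family effects; a negative-binomial
    GLM Wald test with median-of-ratios normalisation, method-of-moments
    dispersion and Benjamini-Hochberg FDR; constrained randomization null
    distributions for differentially-expressed-gene counts; an
    additive/maternal/paternal inheritance-mode classifier for reciprocal
    crosses; KING-robust kinship, Weir-Cockerham FST and genotype filtering
    from VCF input; and k-means summarisation of GO-term semantic maps.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
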