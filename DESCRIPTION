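Package: gobias
Title: Gene Category Enrichment for Count Data with Selection-Bias Correction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Over-representation testing of gene categories (Gene Ontology
    terms, pathways, or arbitrary gene sets) among differentially expressed
    genes called from count-based expression data, correcting for the
    selection bias by which longer or more highly counted genes are more
    likely to be called differentially expressed. The probability of a gene
    being called DE is modelled as a monotone cubic spline of a bias
    covariate (transcript length or total read count); category significance
    is then assessed either by weighted resampling without replacement or by
    a Wallenius non-central hypergeometric approximation. Includes a Poisson
    exact test for two-library differential expression, diagnostics for
    category length bias and method comparison, a fully seeded synthetic
    data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    Matrix,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
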