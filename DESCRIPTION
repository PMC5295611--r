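Package: kinhet
Title: Kinship-Aware Estimation of Gene Diversity and Population
    Differentiation
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Unbiased estimators of gene diversity (expected
    heterozygosity) for samples containing related and inbred individuals
    of any ploidy, including a variant built on the best linear unbiased
    estimator (BLUE) of allele frequencies with weights derived from the
    inverse kinship matrix.  Provides pedigree construction with recursive
    kinship coefficients (autosomal and X-linked), gene-dropping Monte
    Carlo estimation of higher-order identity-by-descent coefficients,
    exact and approximate theoretical variance of the estimators, FST and
    locus-specific branch lengths with a delta-method variance, and a
    seeded simulation framework for bias/variance/MSE experiments on
    samples of related individuals.
License: MIT + file LICENSE
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
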