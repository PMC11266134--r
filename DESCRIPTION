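Package: stackGS
Title: Stacked Generalization for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Genomic selection by stacked generalization: six linear
    genomic-prediction base models (ridge-regression BLUP, GBLUP, and the
    Bayesian alphabet models BayesA, BayesB, BayesC and the Bayesian lasso,
    fitted by single-site Gibbs sampling) feed out-of-fold predictions to a
    single-hidden-layer perceptron meta-model. Includes a genotype/phenotype
    simulator with configurable genotype-class frequencies, marker-effect
    priors and heritability; RKHS kernel regression and bagging comparators;
    and an evaluation suite covering test/train mean squared error, the
    overfitting gap, test power, non-inferiority margins, Wilcoxon
    signed-rank testing with Hodges-Lehmann intervals, and three-way
    superiority/equivalence/inferiority outcome classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
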