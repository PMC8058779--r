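Package: modp
Title: Modular Optimal Discovery Procedure for General Gene Expression Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Significance analysis of gene expression studies with static,
    independent-sampling (time-course or dose-response) and longitudinal
    designs using the modular optimal discovery procedure (mODP). Mean
    responses are modelled with natural cubic regression splines whose
    dimension is chosen by eigen-gene leave-one-out cross-validation; genes
    are clustered into modules by a symmetric Kullback-Leibler distance and
    the mODP statistic borrows strength across co-expressed genes.
    Significance is assessed against a bootstrap empirical null with
    q-values, local false discovery rates and an estimate of the proportion
    of true nulls. Includes voom-style precision weights for RNA-seq
    counts, F-test and moderated F-test comparators, gene-set scoring by
    the proportion of true positives, and a simulation harness for FDR and
    power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    fgsea
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
biocViews: DifferentialExpression, MultipleComparison, TimeCourse,
    RNASeq, Regression, GeneExpression
RoxygenNote: 7.3.3
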