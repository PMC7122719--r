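Package: psychembed
Title: Word-Embedding Summaries of Ordinal Psychiatric Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Summarizes ordinal self-report psychiatric questionnaires as
    word-embedding-based patient vectors. Question texts are embedded as
    IDF-weighted sums of word vectors, survey-level patient vectors as
    response-weighted sums of question vectors, and low-dimensional symptom
    scores are derived by principal components, canonical correlation against
    a 13-domain DSM-style self-rated symptom matrix, and cosine-similarity
    scores for Research Domain Criteria (RDoC) domains. Includes a skip-gram
    negative-sampling trainer for word embeddings, bootstrap evaluation of
    diagnostic contrasts by Gaussian-mixture clustering and cross-validated
    logistic regression, permutation comparison of feature sets, t-SNE
    projection, Spearman association matrices, LASSO regressions with
    AIC-selected penalties, and a synthetic-cohort generator emulating the
    latent-severity structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    mclust,
    glmnet,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
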