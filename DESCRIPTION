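Package: pleiosgl
Title: Sparse Group Multi-Task Logistic Regression for Pleiotropy Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Penalised multi-study logistic regression for detecting
    pleiotropic genetic signals across independent case-control studies.
    Fits a joint likelihood over K studies under a composite sparse-group
    penalty (a group-level G2,1 norm over genes or pathways plus a
    variable-level l2,1 norm over studies), solved by an alternating
    direction method of multipliers (ADMM) with a preconditioned Newton
    inner solver. Includes repeated stratified cross-validation with the
    one-standard-error rule for tuning, bootstrap stability selection,
    adaptive penalty weights, a group-structured simulation benchmark,
    and TSV readers/writers for dosage matrices and group maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
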