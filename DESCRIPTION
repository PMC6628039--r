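Package: knockboost
Title: Knockoff-Based False Discovery Rate Control for Biomarker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Variable selection with finite-sample false discovery rate (FDR)
    control for high-dimensional biomarker discovery. Implements second-order
    Gaussian (model-X) knockoff construction, model-free importance statistics
    based on component-wise gradient boosting with P-spline base-learners
    (risk reduction in boosting, RRB) and on differences in R-squared (DRS),
    the lasso coefficient difference (LCD) baseline, nonlinear B-spline
    screening for the p >> n regime, knockoff(+) thresholding, a gene
    expression prefilter (mean TPM and Benjamini-Hochberg q-value rules), and
    a reproducible simulation suite covering linear, quadratic and Cox
    proportional-hazards survival designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    graphics,
    splines,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
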