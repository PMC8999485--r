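Package: neckprog
Title: Cervical Kinematic and Neuromuscular Features with Neck-Pain Prognosis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying neuromuscular function in recurrent and chronic
    neck pain. Extracts cervical kinematic features (range of motion, mean and
    peak angular velocity, movement smoothness as the number of velocity peaks,
    joint position error) from inertial-sensor angle recordings, and
    neuromuscular features (sliding-window RMS electromyography amplitude
    normalised to maximal voluntary contraction, craniocervical and cervical
    strength) from surface EMG and dynamometer force recordings. Implements a
    distribution-aware three-group comparison tree (Shapiro-Wilk and Levene
    gates into ANOVA, Welch ANOVA or Kruskal-Wallis with Tukey, Games-Howell or
    Dunn post hocs) and a two-step prognostic modelling workflow: LASSO
    predictor shrinkage with cross-validation followed by multivariate ordinary
    least squares with full inferential and internal-validation reporting
    (confidence intervals, adjusted R-squared, F statistic, RMSE). A synthetic
    cohort generator with known ground truth makes every stage testable without
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    car,
    jsonlite,
    ggplot2,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
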