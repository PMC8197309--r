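Package: trajcvd
Title: Joint Trajectory Clustering of Cardiovascular Risk Factors in Worker Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal analysis of cardiovascular risk factor (CVRF)
    trajectories in an occupational cohort observed at three medical
    examinations: synthetic cohort generation with a two-profile Gaussian
    copula and a three-state smoking Markov chain, eligibility filtering,
    bisector/linear-interpolation completion of partially observed
    trajectories, ten-year SCORE cardiovascular risk from the low-risk
    European Weibull equations, stationary Markov projection of smoking
    status, k-means clustering of joint multivariate trajectories with
    Calinski-Harabasz model selection, and quartile/cluster
    characterization tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
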