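Package: starsae
Title: Small Area Estimation of Binary Health Indicators with Structured
    Additive Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unit-level small area estimation for binary health-related
    indicators. Fits penalized Bernoulli-logit structured additive
    regression models combining linear categorical effects, P-splines
    (B-spline bases with difference penalties), and a Markov-random-field
    spatial effect over a neighbourhood adjacency graph, with smoothing
    parameters selected by Laplace-approximate restricted maximum
    likelihood. Individual predictions over a full registry population are
    aggregated into neighbourhood, district and municipality prevalence
    estimates, with observed survey outcomes replacing model predictions
    where available, Monte-Carlo uncertainty quantification, quantile-bin
    calibration assessment, and a synthetic registry/survey/geometry
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    igraph,
    methods,
    nnet,
    splines,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
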