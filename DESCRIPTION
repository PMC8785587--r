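Package: geostunt
Title: Bayesian Geostatistical Modelling of Childhood Stunting from Cluster Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model-based geostatistics for binary childhood stunting outcomes
    recorded in geo-located cluster surveys of the Demographic and Health
    Survey (DHS) type. Simulates DHS-like survey data with a known
    spatially structured Gaussian random field, fits spatial and
    non-spatial Bayesian logistic models by Markov chain Monte Carlo with
    within-chain imputation of missing covariates, checks models with
    conditional predictive ordinates, Bayesian predictive p-values and the
    pseudo marginal likelihood, and predicts the spatially structured
    residual odds-ratio surface with uncertainty on a regular kilometre
    grid by simple kriging of the latent field.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    rjags,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
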