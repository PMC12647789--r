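Package: nrfit
Title: Nutrient-Response Curve Modeling with a Single Tanh Neuron
Version: 0.1.0
Authors@R: person("nrfit", "developers", role = c("aut", "cre"),
    email = "nrfit@example.org")
Description: Fits nutrient-response (dose-response) data with the
    four-parameter sigmoid Response = A*tanh(c*Nutrient + b) + B, a
    one-neuron network trained by Bayesian-regularized
    Levenberg-Marquardt (MacKay evidence framework). Derives closed-form
    nutritional metrics (maximum marginal efficiency, inflection point,
    lag, half-life, asymptote, 95%/99% requirements), quantifies
    uncertainty by proportional-noise data augmentation plus
    non-parametric bootstrap percentile intervals, and compares groups
    via one-way ANOVA on bootstrap distributions with Tukey HSD and
    compact letter displays. Includes a synthetic-data generator, CSV
    readers/report writers, curve and enhanced-boxplot graphics, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
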