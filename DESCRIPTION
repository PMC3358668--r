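Package: sdemc
Title: Statistical Model Checking of Stochastic Differential Equations by
    Biased Sampling and Change of Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Verifies probabilistic temporal-logic properties of stochastic
    differential equation (SDE) models. Trajectories are generated with a
    fixed-step Euler-Maruyama scheme, optionally under randomly perturbed
    (Girsanov-shifted) probability measures that expose rare behaviours;
    each finite trace is monitored against a bounded linear temporal logic
    (BLTL) formula; and a Bayesian sequential hypothesis test decides
    whether the satisfaction probability exceeds a threshold, with the
    Bayes factor conservatively corrected for non-identically distributed
    sampling via a user-asserted fairness bound. Ships two stochastic
    tumor-growth models, analytic benchmarks with known satisfaction
    probabilities, and a discrete fixture with explicit change of measure
    for validating the posterior bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
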