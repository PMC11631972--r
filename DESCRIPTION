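Package: nesbr3
Title: Neutrosophic Burr-III Distribution for Interval-Valued Lifetime Data
Version: 0.1.0
Authors@R:
    person("nesbr3", "maintainers", email = "maintainers@nesbr3.invalid",
           role = c("aut", "cre"))
Description: Distribution functions, closed-form properties, maximum-likelihood
    fitting and model selection for the neutrosophic Burr-III (NeS-BrIII)
    distribution, an interval-valued extension of the two-shape-parameter
    Burr-III lifetime model in which each observation carries an indeterminacy
    interval [I_L, I_N]. Provides density, distribution, quantile, survival,
    hazard and random-variate functions; moments, skewness and kurtosis,
    stress-strength reliability, order statistics and Renyi entropy with
    independent quadrature and simulation oracles; per-endpoint maximum
    likelihood estimation with observed-information standard errors and
    AIC/CAIC/BIC/HQIC model comparison against Burr-XII, Weibull and
    Nadarajah-Haghighi alternatives; a Monte-Carlo simulation harness; bundled
    COVID-19 mortality-rate and analgesic relief-time datasets; and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
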