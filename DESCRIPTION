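Package: audiogp
Title: Gaussian Process Audiometry with Active Tone Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hearing-threshold estimation by Gaussian process binary
    classification over the tone space (frequency by intensity in dB HL).
    A Laplace-approximate logistic GP classifier is fitted to heard/not-heard
    trial tuples; maximally informative tones are selected by Bayesian active
    learning (BALD, predictive entropy or latent variance) until a fixed
    response budget is reached, and the 0.5 decision boundary is extracted as
    a continuous threshold curve with a credible band. Includes simulated
    listeners with psychometric response models, a modified Hughson-Westlake
    staircase comparator, and the statistical pipeline used to compare the
    two methods: per-frequency and pure-tone-average differences, one-sample
    t tests, a Lilliefors normality test with Monte Carlo critical values, a
    MANOVA group-mean dimension test, and Jeffreys-prior credible intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
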