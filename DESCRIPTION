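Package: pollenrisk
Title: Pesticide Mixture Risk in Pollen and Bumble Bee Colony Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toxicity-weighted mixture risk scoring of pesticide residues in
    bee-collected pollen (per-compound toxicity-weighted concentrations,
    additive mixture risk, maximum cumulative ratio and compound risk
    scores), derivation of bumble bee colony performance endpoints (log
    response-ratio weight gain, cocoon production, queen production), and
    hierarchical models linking mixture risk, focal crop and landscape
    cropland to colony outcomes: Gaussian linear mixed models, negative
    binomial and zero-inflated negative binomial generalized linear mixed
    models with site-nested-in-country random intercepts, Wald chi-square
    term tests, variance-partition R-squared, simple slopes, marginal-mean
    contrasts and overdispersion/collinearity diagnostics. Includes a
    synthetic-study generator that emulates a multi-country sentinel-colony
    field design end to end, plus simulation-based power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmmTMB,
    emmeans,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
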