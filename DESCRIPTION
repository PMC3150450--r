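Package: coevo
Title: Analysis of Phage-Host Serial-Passage Coevolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of serial-passage coevolution experiments
    between a lytic bacteriophage and its bacterial host: replication-generation
    bookkeeping from daily passage logs, host and phage fitness statistics from
    cross-coculture assays, infection and adsorption kinetics from hourly time
    courses, polymorphism-weighted mutation accumulation and fixation-rate
    estimation from population sequencing calls, gene-level mutation-bias
    testing, and the associated inferential battery (one-way ANOVA with Tukey
    and Tukey-Kramer post hoc tests, ANCOVA slope comparison, Welch's t, slope
    t-tests, exact two-tailed binomial, Poisson rate comparison). A mechanistic
    simulator of lytic phage-bacteria copropagation (logistic host growth,
    mass-action adsorption, staged latent period, burst, partial resistance,
    daily dilution regimes, and a site-status substitution process) generates
    every input format with known ground truth so all estimators can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    emmeans,
    readr,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
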