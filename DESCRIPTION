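Package: quitdyn
Title: Stage-of-Change Markov Chain and Compartmental ODE Models for
    Smoking Cessation Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step evaluation of behaviour-change interventions from
    panel-observed stage-of-readiness data. A four-stage continuous-time
    Markov chain (unmotivated, indecisive, motivated, former smoker; the
    last absorbing) is fitted by maximum likelihood to interval transition
    counts, giving transition-probability and prevalence curves, sojourn
    times with simulated confidence intervals, and temporal relative
    efficacy and penalized effectiveness metrics. The fitted prevalence
    curves then parametrize a linear compartmental ODE model for
    long-horizon projection, equilibrium and eigenvalue stability
    analysis, average prevalence, and time-to-absorption summaries.
    Includes a synthetic panel generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
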