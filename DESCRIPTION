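Package: npstroop
Title: Connectionist Simulation of Negative Priming in the Stroop Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates Stroop task performance and negative priming (NP) with a
    family of small feedforward connectionist models: a conventional parallel
    distributed processing (PDP) model with running-average dynamics, a refined
    PDP model without any trial-to-trial memory, and a PDP model extended with a
    time-delayed working-memory layer (PDP-WM). Responses and reaction times are
    generated by a noisy evidence accumulator over the output units. The package
    provides the stimulus taxonomy for prime-probe pairs (NP subtypes and their
    feature-non-overlapping controls), backpropagation training of the network,
    a full simulation harness (re-initialised training epochs, randomized Stroop
    test sequences, a working-memory weight sweep, positive-priming checks), and
    the statistical battery used to analyse trial tables (outlier filtering,
    one-way ANOVA, Tukey and Tamhane T2 post-hoc tests, Levene's test,
    independent t-tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
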