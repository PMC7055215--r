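Package: kirbyhorizon
Title: Temporal Discounting and Explore-Exploit Behavior: Questionnaire
    Scoring, Horizon Task Metrics and Choice Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the relationship between temporal
    discounting and explore-exploit behavior. Scores the 27-item monetary
    choice questionnaire into hyperbolic discount rates (overall, per reward
    magnitude, and their geometric mean) by maximum-consistency search over
    item indifference points. Computes model-free Horizon Task measures
    (p(high info), p(low mean), directed and random exploration, accuracy,
    reaction time) and fits a logistic first-free-choice model with an
    information bonus, a spatial bias and decision noise by maximum
    likelihood. Includes a synthetic-data generator with a Gaussian copula
    over latent traits for end-to-end pipeline testing and parameter
    recovery, plus paired-test, effect-size, correlation-table and
    Fisher-z sample-size utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    lhs,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
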