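Package: fittree
Title: Cost-Sensitive Decision Trees for Physical Fitness Test Data
Version: 1.0.0
Authors@R:
    person("fittree", "developers", email = "fittree@example.org", role = c("aut", "cre"))
Description: Tools for analysing student physical-health test records with
    C4.5-style decision trees. Implements the information gain-ratio split
    criterion and a cost-sensitive variant that reweights class probabilities
    by misclassification cost, recursive tree induction with continuous
    threshold search, JSON tree serialization, the national BMI band scoring
    standard for four university grades, a seeded synthetic student-cohort
    generator, and cost-stratified error-rate evaluation for comparing the
    standard and cost-weighted models. Includes a command-line interface
    covering cohort generation, scoring, training, evaluation and model
    comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
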