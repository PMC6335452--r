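Package: precom
Title: Computational Models of Precommitment in Effort- and Delay-Based Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative models of effort-based and delay-based choice with an
    optional precommitment stage, in which an agent may remove a tempting
    effort-free or immediate small reward from its future choice set.
    Implements hyperbolic subjective-value discounting, softmax choice and
    precommitment rules under two competing accounts (motivation maximization
    and willpower suppression), per-subject maximum-likelihood fitting with
    bounded multi-start optimization, BIC and McFadden pseudo-R2 model
    comparison, repeated-measures (GEE-style) logistic regression with QIC
    working-correlation selection, model-free behavioural rates, cross-task
    Spearman correlations, a synthetic-cohort simulator matching the task
    structure, and parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), sandwich, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
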