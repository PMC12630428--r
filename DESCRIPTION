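Package: gcmediate
Title: Counterfactual Mediation Analysis by Parametric G-Computation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates total, natural direct, and natural indirect effects
    of a binary exposure on binary or numeric outcomes through a block of
    sequentially ordered mediators, in the presence of baseline and
    intermediate (exposure-induced) confounders, using the parametric
    g-computation formula with Monte Carlo counterfactual simulation and
    bootstrap normal-based confidence intervals.  Includes an exact
    enumeration oracle for all-binary systems, multivariate imputation by
    chained equations with Rubin's-rules pooling, staged logistic
    association tables, and a synthetic birth-cohort generator with known
    ground truth calibrated to the marginal prevalences of a Brazilian
    birth-cohort study of childhood conduct problems, adolescent snares
    (police arrest, gang membership, school noncompletion), and
    early-adult substance use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
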