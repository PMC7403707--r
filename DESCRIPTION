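Package: plastvec
Title: Vector-Based Meta-Analysis of Plasticity and Local Adaptation in
    Reciprocal Transplant Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how multivariate phenotypic plasticity aligns with
    local adaptation in two-population reciprocal transplant experiments.
    Builds plasticity, total-difference and evolutionary-divergence vectors
    from experimental-unit centroids, derives angle, projection and
    length-based effect sizes with Monte Carlo sampling variances from
    parametric resampling of trait means and P-matrices, and pools effect
    sizes across studies with multilevel random-effects meta-analysis
    (study-level or phylogenetic random effects, REML, AICc model
    comparison). Includes a Hedges' g moderator for the strength of local
    adaptation, a synthetic-data generator with closed-form ground truth
    for validation, and an end-to-end pipeline with an ancestral-order
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    metafor,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
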