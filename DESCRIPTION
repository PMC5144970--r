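Package: plastinorm
Title: Reaction Norm Analysis of Fungal Growth Across Environments
Version: 0.1.0
Authors@R: person("Plastinorm", "Developers", email = "plastinorm@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying phenotypic plasticity of filamentous fungi
    from race-tube growth assays. Estimates mycelial growth rates by linear
    regression of front position on time, builds per-genotype reaction norms
    across environmental gradients (temperature, osmotic stress, sucrose, pH),
    locates environmental optima with natural-spline fits, tests
    genotype-by-environment interaction with mixed models (Type III F-tests
    using a Satterthwaite approximation for denominator degrees of freedom,
    likelihood-ratio chi-square tests for variance components, Holm-adjusted
    pairwise comparisons), and contrasts mutant strains against a control with
    a hierarchical Bayesian one-way model that allows genotype-specific
    variances, reporting 95% highest posterior density intervals. A synthetic
    data generator reproduces the factorial structure of such experiments so
    that every stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    Matrix,
    lme4,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
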