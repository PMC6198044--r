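Package: cuniqg
Title: Quantitative Genetics of Disease Resistance and Production Traits
    in Two-Environment Rabbit Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based quantitative-genetic analysis of binary disease
    resistance and production traits recorded in a selection and a challenging
    environment, as practised in maternal rabbit lines. Provides pedigree
    ingestion with numerator relationship matrices and their sparse inverses,
    a synthetic-data generator emulating the two-environment sib-testing
    design, REML estimation for multi-trait linear animal models with
    maternal and common-litter effects, penalized quasi-likelihood threshold
    (liability) models with a logit link for binary traits, genotype-by-
    environment genetic correlations with boundary likelihood-ratio tests,
    sampling-based standard errors of heritabilities, breeding-objective
    covariance algebra with a desired-gains weight search, and deterministic
    pseudo-BLUP prediction of multi-trait selection response under the Bulmer
    equilibrium for alternative breeding schemes and recording strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    lme4,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
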