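Package: gencovsem
Title: Genetic Covariance Structural Equation Modeling from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("gencovsem", "developers", email = "gencovsem@example.org", role = c("aut", "cre"))
Description: Estimates multi-trait genetic covariance matrices from GWAS
    summary statistics via LD-score regression with a block-jackknife
    sampling covariance, and fits latent-factor structural equation models
    to the resulting (S, V) pair by diagonally weighted least squares with
    sandwich standard errors and standard fit indices (chi-square, CFI,
    SRMR, AIC). Includes readers and harmonization for summary-statistics
    tables, LD-score computation from a reference dosage panel, a
    declarative model syntax, pre-built correlated-factor and
    multiple-regression models linking anorexia nervosa to impulsivity
    facets and substance use disorders, a simulator of factor-structured
    summary statistics for end-to-end validation, and a configuration
    driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
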