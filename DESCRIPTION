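Package: sevsem
Title: Structural Equation Modeling of Alcohol Use Disorder Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariance-structure (structural equation) modeling of alcohol use
    disorder severity. Implements a lavaan-style model syntax over RAM matrices,
    maximum-likelihood estimation of latent-variable models from covariance or
    correlation+SD input, standardized solutions with latent R-squared,
    chi-square based fit indices (relative chi-square, CFI, RMSEA),
    Satorra-Bentler scaled statistics and sandwich robust standard errors from
    raw data, multi-group estimation with cross-group equality constraints and
    Lagrange multiplier release tests, and a Vale-Maurelli/Fleishman generator
    for non-normal synthetic samples. Ships the published moment table of a
    community sample of problem drinkers (n = 283) and one-command reproduction
    of the four-factor severity model fitted to it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Matrix, pracma, jsonlite, yaml, withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'fit.R'
    'indices.R'
    'io.R'
    'multigroup.R'
    'pipeline.R'
    'ram.R'
    'robust.R'
    'sevsem-package.R'
    'syntax.R'
    'synthetic.R'
    'utils-matrix.R'
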