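Package: prte
Title: Ridge-Type Shrinkage Estimation for Poisson Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Shrinkage estimation for Poisson regression models under
    multicollinearity. Fits the Poisson GLM by iteratively reweighted least
    squares and implements the ridge, Liu, Liu-type, two-parameter and
    related biased estimators together with a general ridge-type family
    driven by a biasing function g(k). Provides closed-form asymptotic
    matrix and scalar mean squared error (MMSE/SMSE) machinery, a catalogue
    of biasing-parameter selection rules, superiority checks based on
    positive definiteness of MMSE differences, a Monte Carlo harness for
    estimated-MSE comparisons on collinear designs, and a bootstrap SMSE
    evaluator for real count datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
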