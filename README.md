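# prte: ridge-type shrinkage estimation for Poisson regression

Count-data regressions — disease incidence on exposure covariates,
damage or event counts on operating conditions — are fitted as Poisson
GLMs, `y_i ~ Poisson(exp(x_i' beta))`. When the covariates are nearly
collinear, the weighted information matrix `X'WX` is ill conditioned and
the maximum likelihood estimator becomes wildly variable. `prte` is for
analysts and methodologists working in that regime: it implements the
classical shrinkage remedies for the Poisson GLM (ridge, Liu, Liu-type,
two-parameter, and the PHY/PSK two-parameter hybrids) together with a
general **ridge-type family**

```
beta_PRTE = (X'WX + I)^-1 (X'WX + g(k) I) beta_ridge(k),
```

in which a single continuous biasing function `g(k)` steers the
bias–variance trade-off. With linear `g(k) = a k + b` the family contains
the MLE, the ridge, the Liu, and the PHY/PSK estimators as exact special
cases, and its scalar risk can be made approximately stationary in `k` by
closed-form linear rules — the basis of the data-driven `PRTE I–IV`
selection rules shipped in the package.

Alongside the estimators the package provides:

* an IRLS fitter with step-halving and full convergence reporting
  (`fit_poisson_mle()`), canonical eigen-coordinates
  (`canonical_decompose()`), and multicollinearity diagnostics
  (`condition_number()`);
* exact asymptotic risk machinery — matrix and scalar mean squared error,
  bias decompositions, risk derivatives, and a positive-definiteness
  superiority test between families (`mmse_matrix()`, `smse()`,
  `smse_derivative()`, `prte_superiority()`);
* a catalogue of biasing-parameter estimators (`estimate_k()`,
  `estimate_d()`, `make_g_rule()`, `phy_strategy()`);
* a Monte Carlo harness for collinear Poisson designs with estimated-MSE
  tables and k-sweep curves (`generate_design()`, `run_scenario()`,
  `emse_table()`);
* a case-bootstrap SMSE evaluator for real datasets (`bootstrap_smse()`)
  and CSV/JSON I/O plus synthetic fixture generators (`read_count_csv()`,
  `generate_fixture()`).

A thin command-line wrapper over these functions is installed at
`inst/scripts/prte-cli.R` (commands `fit`, `simulate`, `sweep`,
`bootstrap`, `compare`).

## Worked example

Fit a strongly collinear synthetic count dataset, diagnose the
conditioning, and apply the ridge-type estimator with its first selection
rule:

```r
library(prte)

d   <- generate_fixture("collinear_toy", seed = 42, rho = 0.99)
ds  <- standardize_dataset(d)
fit <- fit_poisson_mle(ds)
fit
#> Poisson GLM fit (IRLS): n = 50, p = 3, converged in 6 iteration(s)
#> Coefficients:
#> (Intercept)          x1          x2          x3
#>     -0.2535      2.7430      7.5723      0.8362
#> log-likelihood: -61.4120   sigma2_hat: 2.3422

canon <- canonical_decompose(fit)
max(canon$lambda) / min(canon$lambda)
#> [1] 2760.31          # >> 30: severe multicollinearity

inp  <- biasing_inputs(fit, canon)
k    <- estimate_k("k_PRTE_I", inp)       # 10.1842
rule <- make_g_rule("PRTE_I", inp)
rule
#> gk_rule [PRTE_I]: g(k) = 8.45491e-05 k + -0.0461359

prte(shrinkage_spec("PRTE", k = k, rule = rule), fit)
#> (Intercept)          x1          x2          x3
#>      1.1414      0.9282      0.9320      0.9411
```

The MLE's standardized-scale coefficients (up to 7.6) are an artefact of
the near-singular design; the ridge-type estimate pulls them back to a
stable configuration. A small Monte Carlo comparison at the same
collinearity level shows why:

```r
run_scenario(50, 2, 0.99, n_rep = 500, seed = 1,
             estimators = c("MLE", "PRE", "PLE", "PRTE_I"))$emse
#>     MLE     PRE     PLE  PRTE_I
#> 38.0583  0.4701  0.3679  0.3222
```

The estimated MSE of the MLE is two orders of magnitude above the
shrinkage estimators, and the ridge-type rule improves on both the ridge
and Liu baselines.

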