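---
title: "Ridge-type shrinkage estimation for Poisson regression under multicollinearity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ridge-type shrinkage estimation for Poisson regression under multicollinearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prte)
```

## The problem

Count responses modelled as $y_i \sim \mathrm{Poisson}(\mu_i)$ with the
canonical log link $\mu_i = \exp(x_i'\beta)$ are routinely fitted by maximum
likelihood via iteratively reweighted least squares (IRLS),

$$\hat\beta_{MLE} = (X'\hat W X)^{-1} X'\hat W Z, \qquad
\hat W = \mathrm{diag}(\hat\mu_i), \quad
z_i = \log\hat\mu_i + \frac{y_i - \hat\mu_i}{\hat\mu_i}.$$

When the columns of $X$ are nearly linearly dependent the weighted
information matrix $X'\hat W X$ has one or more tiny eigenvalues, the
asymptotic covariance $(X'\hat W X)^{-1}$ blows up along those directions,
and the MLE becomes unstable. The standard remedies transplant the ridge
and Liu shrinkage ideas from linear regression into the GLM: with
$S = X'\hat W X$ and $b = \hat\beta_{MLE}$,

| family | estimator | biasing parameters |
|---|---|---|
| PRE (ridge) | $(S + kI)^{-1} S\, b$ | $k > 0$ |
| PLE (Liu) | $(S + I)^{-1}(S + dI)\, b$ | $0 < d < 1$ |
| PLTE (Liu-type) | $(S + kI)^{-1}(S - dI)\, b$ | $k > 0$, $d \in \mathbb{R}$ |
| PTPE (two-parameter) | $(S + kI)^{-1}(S + kdI)\, b$ | $k > 0$, $0 < d < 1$ |
| PHY | $(S + I)^{-1}(S + dI)\,\hat\beta_{PRE}$ | $k > 0$, $0 < d < 1$ |
| PSK | $(S + I)^{-1}(S + (k+d)I)\,\hat\beta_{PRE}$ | $k > 0$, $d \in \mathbb{R}$ |
| ILTE | $(S + kI)^{-1}(S + f(k)I)\, b^{*}$ | rule $f(k)$, base $b^{*}$ |
| PRTE (ridge-type) | $(S + I)^{-1}(S + g(k)I)\,\hat\beta_{PRE}$ | rule $g(k)$ |

The package's centrepiece is the last row: a *general ridge-type family*
driven by a single continuous biasing function $g(k)$. With a linear rule
$g(k) = ak + b$ it contains the MLE ($k = 0$, $b = 1$), the ridge estimator
($g \equiv 1$), the Liu estimator ($k = 0$, $b = d$), the PHY family
($a = 0$) and the PSK family ($a = 1$) as exact special cases — identities
that the test suite verifies to $10^{-12}$ at both the estimator and the
risk level.

## Canonical coordinates and asymptotic risk

Every family maps the MLE linearly, $\hat\beta = H\,\hat\beta_{MLE}$, with
$H$ a function of $S$ alone. Writing $S = Q\Lambda Q'$ (eigenvalues
$\lambda_1 \ge \dots \ge \lambda_{p+1} > 0$) and
$\alpha = Q'\beta$, every $H$ is diagonal in the eigenbasis, so the
asymptotic matrix mean squared error

$$\mathrm{MMSE}(\hat\beta) = H (X'\hat WX)^{-1} H' + (H - I)\beta\beta'(H-I)'$$

reduces to diagonal sums. For the ridge-type family with factors
$h_j = \lambda_j(\lambda_j + g(k)) / ((\lambda_j+1)(\lambda_j+k))$,

$$\mathrm{SMSE}(\hat\beta_{PRTE}) = \underbrace{\sum_j
\frac{\lambda_j(\lambda_j+g(k))^2}{(\lambda_j+1)^2(\lambda_j+k)^2}}_{\text{variance}}
+ \underbrace{\sum_j \frac{((g(k)-k-1)\lambda_j - k)^2\,\alpha_j^2}
{(\lambda_j+1)^2(\lambda_j+k)^2}}_{\text{squared bias}},$$

and $\mathrm{SMSE} = \mathrm{tr}(\mathrm{MMSE})$ throughout. `mmse_matrix()`
and `smse()` evaluate these; `prte_superiority()` decides whether
$\mathrm{MMSE}(\hat\beta_{ILTE}) - \mathrm{MMSE}(\hat\beta_{PRTE})$ is
positive definite via the interval-plus-quadratic-form characterization,
with a direct eigenvalue check carried alongside. Positive definiteness is
declared when the smallest eigenvalue of the symmetrized matrix exceeds a
tolerance, $10^{-12}$ by default. Two numerical points are worth recording:

* the matrix difference characterized by the superiority theorem omits the
  ILTE's own (positive semidefinite) bias term, so its verdict is
  *conservative* for the full MMSE gap — the tests assert the implication
  explicitly;
* the strict form of the quadratic-form threshold ($< 1$) is used, matching
  the strict positive-definiteness it characterizes.

## Choosing g(k): stationarity of the risk

Differentiating $h(k) = \mathrm{SMSE}(\hat\beta_{PRTE})$ in $k$
(`smse_derivative()`) gives a sum whose $j$-th term factorizes. Each factor
vanishes on a family of *lines* in the $(k, g)$ plane:

* $g(k) = ck + (c-1)\lambda_j$ for any constant $c$ (the integration
  constant of the stationarity differential equation), and
* $g(k) = \frac{\alpha_j^2(\lambda_j+1)}{1 + \lambda_j\alpha_j^2}\,k +
  \left(\frac{\alpha_j^2(\lambda_j+1)}{1 + \lambda_j\alpha_j^2} - 1\right)\lambda_j$,

which is why the practical rules in `make_g_rule()` are all linear with
intercept $(\text{slope}-1)\lambda_{\min}$: they make the risk
approximately stationary for the dominant component while keeping
$g(0) \ge -\lambda_{\min}$, so the shrinkage factor of every component
stays well behaved. On a single-component system both lines zero the
derivative *identically* — a property the tests check by central finite
differences.

A dimension convention matters here: the published plug-in rules are
written with a factor "$p$" but sum over the canonical components. This
package consistently uses the *component count* $m = p + 1$ for the
dimension factor in the `k_PRTE_*` rules and the `PRTE_II` slope, and runs
all sums, maxima and medians over the full set of canonical components;
that convention reproduces the published plug-in values on the classic
aircraft-damage data (e.g. $\hat k = m(\lambda_{\max} -
\lambda_{\min})/n$).

Degenerate inputs: a zero canonical coefficient makes $m_j =
\sqrt{\hat\sigma^2/\hat\alpha_j^2}$ infinite; such components drop out of
maximum rules and are skipped (with a warning) by the geometric-mean rule.
Rules that can turn non-positive on extreme spectra (`k_PLTE_II`,
`k_PRTE_I`) are floored at `.Machine$double.eps * lambda_max` with a
warning rather than erroring, because the downstream matrix formulas
require $k > 0$.

The PHY family needs a $(k, d)$ pair; its published selection methods are
defined in external work, so the pair is pluggable (`phy_strategy()`). The
package's own defaults combine the Hoerl–Kennard ($\hat\sigma^2 /
\hat\alpha_{\max}^2$) and Hoerl–Kennard–Baldwin
($m\hat\sigma^2/\sum\hat\alpha_j^2$) ridge parameters with the closed-form
$d$ minimizing the family's quadratic-in-$d$ SMSE, clipped to $[0, 1]$.

## Fitting: numerical choices

`fit_poisson_mle()` starts IRLS from the least-squares regression of
$\log(y + 0.5)$ on the design (the offset guards $\log 0$), declares
convergence when the largest absolute coefficient change drops below
$10^{-8}$ (the strictest common reading of "difference between old and
updated values"), and halves any step that would decrease the
log-likelihood, at most ten times per iteration. Non-convergence is a
reported status, never silent. The residual variance feeding the biasing
rules is computed on the response scale,
$\hat\sigma^2 = \sum_i (y_i - \hat\mu_i)^2/(n - p - 1)$.

Eigenvalue ties in `canonical_decompose()` are resolved by a sign
convention (first non-zero eigenvector entry positive), which makes the
canonical coefficients reproducible. The condition number is the plain
eigenvalue ratio $\lambda_{\max}/\lambda_{\min}$, not its square root.

All estimator formulas are evaluated by symmetric positive definite solves
of $(S + cI)$; explicit inverses appear only in the exported covariance
and induced-map matrices. The induced map $H = Q\,\mathrm{diag}(h_j)\,Q'$
is exposed separately (`induced_map()`) precisely so the two code paths can
be cross-checked, which the tests do to $10^{-12}$.

## What the Monte Carlo harness emulates

`generate_design()` builds covariates as
$x_{ij} = (1-\rho^2)^{1/2} w_{ij} + \rho\, w_{i,p+1}$ from i.i.d. standard
normal draws, so any two covariates correlate at $\rho^2$; the studied
levels are $\rho \in \{0.85, 0.9, 0.99, 0.999\}$. Three design choices
deserve explanation because they are inferences, not arbitrary knobs:

* **Columns are centred and scaled to unit length.** Under this convention
  the spectrum of $X'\hat WX$ — and with it every risk in the study — is
  governed by $\rho$ and $p$, not by $n$, which is the regime in which the
  biasing parameter $k$ is comparable across scenarios. The flag
  `standardize = FALSE` restores raw columns.
* **The fitted model has no intercept.** The generating intercept is zero
  and the simulated model is the $p$-dimensional model. With an intercept
  column the dominant eigenvalue of $X'\hat WX$ (of order $n$) belongs to
  the constant direction, which carries no signal; the
  $\lambda_{\max}$-based selection rules would then key on an
  uninformative direction and the ridge-type family loses its edge. In the
  no-intercept model $\lambda_{\max}$ belongs to the principal covariate
  axis — exactly the direction the true coefficient vector is aligned
  with. `intercept = TRUE` switches to the (p+1)-dimensional variant.
* **One design per scenario.** $X$ is drawn once per $(n, p, \rho)$ and
  held fixed; only the responses are redrawn across the $N$ replications.
  A consequence is that single EMSE values inherit the variability of that
  one design draw — cells driven by $1/\lambda_{\min}$ (the MLE and the
  Liu-type pairings built on extreme spectra) can vary by a factor of
  2–3 across design draws at $\rho = 0.99$. The acceptance checks
  therefore average cells over design seeds and phrase the headline claim
  (every ridge-type rule beating every competitor) as a per-seed ordering
  that must hold on at least 90% of seeds. `fresh_design = TRUE` redraws
  $X$ per replication instead.

The true coefficient vector is the unit-norm principal eigenvector of
$X'X$, the alignment that maximizes collinearity damage; per-replication
seeds are derived deterministically from the master seed so a dropped
(non-converged) replication never shifts later draws. Replications that
fail to converge are dropped and counted; a scenario with more than 10%
failures is flagged.

What the generator does *not* emulate: overdispersion, exposure offsets,
heavy-tailed or discrete covariates, model misspecification. Passing tests
therefore demonstrate correctness of the estimators and risk machinery
under the stated Gaussian-design Poisson model, not robustness of the
ridge-type family on arbitrary real data.

Problem sizes used by the default test and acceptance runs — chosen as the
smallest sizes at which the Monte Carlo error is clearly below the decision
margins — are $N = 2000$ replications per scenario, 10–20 design seeds per
claim, $10^6$ draws for the sampling oracle of the risk formulas, and
$10^4$ random instances for the superiority cross-check.

## Bootstrap evaluation on real data

`bootstrap_smse()` implements a case bootstrap: rows are resampled with
replacement, each resample is (by default) re-standardized and refitted,
and each estimator — including the re-estimation of its biasing
parameters, so the reported risk reflects the whole pipeline's variability
(`refit_rules = FALSE` freezes them at full-data values) — is evaluated.
The reference vector is the mean of the bootstrap MLEs, so the MLE's own
bootstrap SMSE equals its bootstrap variance, and every estimator's SMSE
decomposes exactly as variance plus squared bias to that reference. Rank
deficient resamples are redrawn up to ten times, then skipped and counted.

A subtlety worth knowing: because the reference is the *MLE* mean, a
heavily shrunken estimator can show a large SMSE purely through its bias
to the MLE even when its variance is tiny. On strongly collinear data with
large fitted coefficients this is the expected behaviour, not a bug.

## Known limitations

* Risks are first-order asymptotic; no exact finite-sample MSE.
* No offsets/exposures, no dispersion modelling, no non-canonical links,
  no negative-binomial extension.
* The PHY biasing-pair defaults are this package's choices; they are not
  the externally published (K1, D1)/(K2, D2) methods.
* Biasing-rule plug-ins use estimated $\hat\alpha$, $\hat\sigma^2$; their
  sampling noise is part of the reported EMSEs, as in any plug-in study.
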