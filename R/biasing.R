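#' Inputs for biasing-parameter selection rules
#'
#' Collects the quantities every k/d selection rule is written in terms of:
#' the eigenvalues `lambda` of the weighted information matrix, the
#' canonical coefficients `alpha`, the residual variance `sigma2`, and the
#' derived quantities `m_j = sqrt(sigma2 / alpha_j^2)` (set to `Inf` where
#' `alpha_j = 0`, so `1/m_j = 0` drops out of maxima).
#'
#' @param fit a converged `poisson_fit`, or a `canonical_form` carrying
#'   `n`, `p` and `sigma2` (see [canonical_form()]).
#' @param canon optional pre-computed `canonical_form` for the fit.
#' @return object of class `biasing_inputs` with fields `lambda`, `alpha`,
#'   `sigma2`, `m`, `n`, `p`.
#' @export
biasing_inputs <- function(fit, canon = NULL) {
  if (inherits(fit, "canonical_form")) {
    canon <- fit
  } else {
    stopifnot(inherits(fit, "poisson_fit"))
    if (is.null(canon)) canon <- canonical_decompose(fit)
  }
  if (is.null(canon$sigma2) || is.null(canon$n)) {
    stop("canonical form must carry n and sigma2 for biasing rules", call. = FALSE)
  }
  m <- ifelse(canon$alpha == 0, Inf, sqrt(canon$sigma2 / canon$alpha^2))
  structure(list(lambda = canon$lambda, alpha = canon$alpha,
                 sigma2 = canon$sigma2, m = m, n = canon$n, p = canon$p),
            class = "biasing_inputs")
}

k_rule_names <- c("k_PRE_kibria", "k_PLTE_I", "k_PLTE_II", "k_PLTE_III",
                  "k_PSK", "k_PRTE_I", "k_PRTE_II", "k_PRTE_III", "k_PRTE_IV",
                  "k_PRTE_range", "k_PRTE_maxratio", "k_PRTE_geom")
d_rule_names <- c("d_PLE_qasim", "d_PLTE_ratio", "d_PLTE_halfmin", "d_PSK")
g_rule_names <- c("g1", "g2", "g3", "fact2_line",
                  "PRTE_I", "PRTE_II", "PRTE_III", "PRTE_IV")

clamp_k <- function(k, lambda_max, rule_name) {
  if (!is.finite(k) || k <= 0) {
    floor_k <- .Machine$double.eps * lambda_max
    warning(sprintf("rule %s produced a non-positive k (%.4g); clamped to %.4g",
                    rule_name, k, floor_k), call. = FALSE)
    k <- floor_k
  }
  k
}

#' Estimate the ridge biasing parameter k
#'
#' Catalogue of plug-in estimators of k, each a closed-form function of the
#' eigenvalues and canonical coefficients. All sums, maxima and medians run
#' over the full set of canonical components, and the dimension factor `m`
#' in the rules below is the component count `m = p + 1` (the rules are
#' sometimes quoted over the p slope components only; the full range
#' matches the (p+1)-dimensional estimators and reproduces the published
#' plug-in values, see the methods vignette). Rules that can go
#' non-positive on extreme inputs are floored at
#' `.Machine$double.eps * lambda_max` with a warning, since the downstream
#' formulas require `k > 0`.
#'
#' \describe{
#'   \item{k_PRE_kibria, k_PLTE_I, k_PSK}{`max_j(1/m_j)` with
#'     `m_j = sqrt(sigma2/alpha_j^2)` — the maximum rule for the ridge
#'     parameter.}
#'   \item{k_PLTE_II}{`(lambda_max - 100 lambda_min)/99`.}
#'   \item{k_PLTE_III}{average of
#'     `(lambda_j - d(1 + lambda_j alpha_j^2)) / (lambda_j alpha_j^2)` with
#'     d from the half-minimum rule.}
#'   \item{k_PRTE_I}{`(m lambda_max - (m+1) lambda_min)/n`.}
#'   \item{k_PRTE_II}{`m lambda_max alpha2_med / (n alpha2_mean)`.}
#'   \item{k_PRTE_III, k_PRTE_range}{`m (lambda_max - lambda_min)/n`.}
#'   \item{k_PRTE_IV}{`m max_j(lambda_j alpha_j^2) / (n alpha2_mean)`.}
#'   \item{k_PRTE_maxratio}{`max_j(lambda_j alpha_j^2) / sum_j alpha_j^2`.}
#'   \item{k_PRTE_geom}{geometric mean of `1/|alpha_j|` (zero components
#'     skipped with a warning).}
#' }
#'
#' @param rule_name one of the catalogue names above.
#' @param inputs a `biasing_inputs` object.
#' @return a positive scalar k.
#' @export
estimate_k <- function(rule_name, inputs) {
  stopifnot(inherits(inputs, "biasing_inputs"))
  if (!rule_name %in% k_rule_names) {
    stop(sprintf("unknown k rule '%s'; available: %s", rule_name,
                 paste(k_rule_names, collapse = ", ")), call. = FALSE)
  }
  lam <- inputs$lambda
  a2 <- inputs$alpha^2
  n <- inputs$n
  m <- length(lam)  # component count p + 1: the dimension the rules scale by
  lmax <- max(lam)
  lmin <- min(lam)
  k <- switch(rule_name,
    k_PRE_kibria = ,
    k_PLTE_I = ,
    k_PSK = max(1 / inputs$m),
    k_PLTE_II = (lmax - 100 * lmin) / 99,
    k_PLTE_III = {
      d <- estimate_d("d_PLTE_halfmin", inputs)
      mean((lam - d * (1 + lam * a2)) / (lam * a2))
    },
    k_PRTE_I = (m * lmax - (m + 1) * lmin) / n,
    k_PRTE_II = m * lmax * stats::median(a2) / (n * mean(a2)),
    k_PRTE_III = ,
    k_PRTE_range = m * (lmax - lmin) / n,
    k_PRTE_IV = m * max(lam * a2) / (n * mean(a2)),
    k_PRTE_maxratio = max(lam * a2) / sum(a2),
    k_PRTE_geom = {
      nz <- a2 > 0
      if (!all(nz)) {
        warning("geometric-mean k rule: skipping zero canonical components",
                call. = FALSE)
      }
      exp(mean(log(1 / sqrt(a2[nz]))))
    }
  )
  clamp_k(k, lmax, rule_name)
}

#' Estimate the Liu-type biasing parameter d
#'
#' \describe{
#'   \item{d_PLE_qasim}{`max(0, min_j((alpha_j^2 - 1) / (1/lambda_min +
#'     alpha2_max)))` — clipped at zero by construction; a warning is issued
#'     if the result reaches 1 (outside the Liu admissible range).}
#'   \item{d_PLTE_ratio}{ratio-of-sums rule
#'     `sum_j (1 - k alpha_j^2)/(lambda_j + k)^2 /
#'      sum_j (1 + lambda_j alpha_j^2)/(lambda_j (lambda_j + k)^2)`
#'     (requires `k`).}
#'   \item{d_PLTE_halfmin}{`min_j(lambda_j / (1 + lambda_j alpha_j^2)) / 2`.}
#'   \item{d_PSK}{ratio rule
#'     `sum_j lambda_j(alpha_j^2 - 1)/((lambda_j+1)^2 (lambda_j+k)^2) /
#'      sum_j lambda_j(1 + lambda_j alpha_j^2)/((lambda_j+1)^2 (lambda_j+k)^2)`
#'     (requires `k`).}
#' }
#'
#' @param rule_name one of the catalogue names above.
#' @param inputs a `biasing_inputs` object.
#' @param k ridge parameter, required by the k-dependent rules.
#' @return a scalar d.
#' @export
estimate_d <- function(rule_name, inputs, k = NULL) {
  stopifnot(inherits(inputs, "biasing_inputs"))
  if (!rule_name %in% d_rule_names) {
    stop(sprintf("unknown d rule '%s'; available: %s", rule_name,
                 paste(d_rule_names, collapse = ", ")), call. = FALSE)
  }
  lam <- inputs$lambda
  a2 <- inputs$alpha^2
  if (rule_name %in% c("d_PLTE_ratio", "d_PSK") && is.null(k)) {
    stop(sprintf("rule %s requires k", rule_name), call. = FALSE)
  }
  d <- switch(rule_name,
    d_PLE_qasim = {
      val <- max(0, min((a2 - 1) / (1 / min(lam) + max(a2))))
      if (val >= 1) {
        warning("d_PLE_qasim produced d >= 1, outside the Liu admissible range",
                call. = FALSE)
      }
      val
    },
    d_PLTE_ratio = sum((1 - k * a2) / (lam + k)^2) /
      sum((1 + lam * a2) / (lam * (lam + k)^2)),
    d_PLTE_halfmin = min(lam / (1 + lam * a2)) / 2,
    d_PSK = sum(lam * (a2 - 1) / ((lam + 1)^2 * (lam + k)^2)) /
      sum(lam * (1 + lam * a2) / ((lam + 1)^2 * (lam + k)^2))
  )
  d
}

#' Construct a data-driven g(k) rule
#'
#' Builds the linear biasing-function rules for the ridge-type family. All
#' rules have the form `g(k) = a k + (a - 1) lambda_ref` with `a >= 0`, so
#' `g(0) >= -lambda_ref >= -lambda_min` and the shrinkage factor
#' `(lambda_j + g(k))` stays well behaved; this is asserted at construction.
#'
#' \describe{
#'   \item{g1}{slope `c` (the integration constant, required in (0, 1)),
#'     reference eigenvalue `lambda_min`.}
#'   \item{g2, PRTE_I}{slope
#'     `(1 + lambda_min) alpha2_min / (1 + lambda_max alpha2_max)`.}
#'   \item{PRTE_II}{slope
#'     `(1 + lambda_max) alpha2_min / (m (1 + lambda_max alpha2_max))` with
#'     `m = p + 1` the component count.}
#'   \item{g3, PRTE_III}{slope
#'     `min_j((1 + lambda_j) alpha_j^2) / (n max_j(1 + lambda_j alpha_j^2))`.}
#'   \item{PRTE_IV}{slope
#'     `min_j((1 + lambda_j) alpha_j^2 / (n (1 + lambda_j alpha_j^2)))`.}
#'   \item{fact2_line}{the stationarity line of component `j`: slope
#'     `alpha_j^2 (lambda_j + 1) / (1 + lambda_j alpha_j^2)`, reference
#'     eigenvalue `lambda_j`. On a single-component system this line makes
#'     the SMSE derivative vanish identically.}
#' }
#'
#' @param rule_name one of `"g1"`, `"g2"`, `"g3"`, `"fact2_line"`,
#'   `"PRTE_I"`, `"PRTE_II"`, `"PRTE_III"`, `"PRTE_IV"`.
#' @param inputs a `biasing_inputs` object.
#' @param c integration constant for `"g1"`, in (0, 1).
#' @param j component index for `"fact2_line"`.
#' @return a linear [g_rule()].
#' @export
make_g_rule <- function(rule_name, inputs, c = NULL, j = NULL) {
  stopifnot(inherits(inputs, "biasing_inputs"))
  if (!rule_name %in% g_rule_names) {
    stop(sprintf("unknown g rule '%s'; available: %s", rule_name,
                 paste(g_rule_names, collapse = ", ")), call. = FALSE)
  }
  lam <- inputs$lambda
  a2 <- inputs$alpha^2
  n <- inputs$n
  m <- length(lam)
  lmin <- min(lam)
  lmax <- max(lam)
  a2min <- min(a2)
  a2max <- max(a2)
  lref <- lmin
  slope <- switch(rule_name,
    g1 = {
      if (is.null(c) || c <= 0 || c >= 1) {
        stop("g1 requires an integration constant c in (0, 1)", call. = FALSE)
      }
      c
    },
    g2 = ,
    PRTE_I = (1 + lmin) * a2min / (1 + lmax * a2max),
    PRTE_II = (1 + lmax) * a2min / (m * (1 + lmax * a2max)),
    g3 = ,
    PRTE_III = min((1 + lam) * a2) / (n * max(1 + lam * a2)),
    PRTE_IV = min((1 + lam) * a2 / (n * (1 + lam * a2))),
    fact2_line = {
      if (is.null(j) || j < 1 || j > length(lam)) {
        stop("fact2_line requires a component index j", call. = FALSE)
      }
      lref <- lam[j]
      a2[j] * (lam[j] + 1) / (1 + lam[j] * a2[j])
    }
  )
  stopifnot(slope >= 0)  # guarantees g(0) >= -lambda_min
  g_rule(slope = slope, intercept = (slope - 1) * lref,
         form = if (rule_name == "fact2_line") "fact2_line" else "linear",
         provenance = rule_name, c = c)
}

#' Biasing-parameter strategies for the PHY family
#'
#' The PHY family needs a (k, d) pair. The package registers two default
#' strategies built from classical ridge-parameter estimators combined with
#' the closed-form SMSE-minimizing d given k: `"HK"` uses
#' `k = sigma2 / alpha2_max` and `"HKB"` uses
#' `k = (p+1) sigma2 / sum(alpha_j^2)`. For a given k the PHY shrinkage
#' factor is linear in d, so the SMSE is an exactly minimizable quadratic;
#' the minimizer is clipped into [0, 1], the family's admissible range. A
#' `"custom"` strategy accepts a user function `inputs -> list(k, d)`,
#' making the pair fully pluggable.
#'
#' @param name `"HK"`, `"HKB"` or `"custom"`.
#' @param fun for `"custom"`: function taking a `biasing_inputs` and
#'   returning `list(k = , d = )`.
#' @return a function `inputs -> list(k, d)`.
#' @export
phy_strategy <- function(name = c("HK", "HKB", "custom"), fun = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    stopifnot(is.function(fun))
    return(fun)
  }
  function(inputs) {
    stopifnot(inherits(inputs, "biasing_inputs"))
    a2 <- inputs$alpha^2
    lam <- inputs$lambda
    k <- switch(name,
      HK = inputs$sigma2 / max(a2),
      HKB = (inputs$p + 1) * inputs$sigma2 / sum(a2))
    k <- clamp_k(k, max(lam), paste0("phy_", name))
    cj <- lam / ((lam + 1) * (lam + k))
    d <- (sum(cj * a2) - sum(cj^2 * (1 + lam * a2))) /
      sum(cj^2 * (1 + lam * a2) / lam)
    list(k = k, d = min(max(d, 0), 1))
  }
}

#' The k-sweep estimator triplet
#'
#' Returns the three rule-driven estimators compared along a grid of k
#' values: the improved Liu-type estimator on the MLE with a linear f, the
#' same family on the ridge estimator with the quadratic f that minimizes
#' its SMSE, and the ridge-type estimator with the `g2` line. All three
#' rules are functions of the eigenvalue/canonical-coefficient summaries in
#' `inputs`.
#'
#' @param inputs a `biasing_inputs` object.
#' @return named list of [g_rule()] objects `f_ilte`, `f_ilte_pre`,
#'   `g_prte`.
#' @export
sweep_rules <- function(inputs) {
  stopifnot(inherits(inputs, "biasing_inputs"))
  lam <- inputs$lambda
  a2 <- inputs$alpha^2
  lmin <- min(lam)
  lmax <- max(lam)
  a2min <- min(a2)
  a2max <- max(a2)
  s1 <- lmin * a2min / (1 + lmax * a2max)
  A <- a2min / (1 + lmax * a2max)
  list(
    f_ilte = g_rule(slope = s1, intercept = (s1 - 1) * lmin,
                    provenance = "sweep_ilte"),
    f_ilte_pre = g_rule(form = "quadratic", provenance = "sweep_ilte_pre",
                        fun = function(k) A * (k + lmin)^2 - (k + lmin)),
    g_prte = make_g_rule("g2", inputs)
  )
}
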