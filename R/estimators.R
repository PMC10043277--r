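#' Biasing-function rule g(k) / f(k)
#'
#' The general ridge-type and improved Liu-type estimator families are driven
#' by a continuous function of the biasing parameter k. In practice the
#' function is linear, `g(k) = a k + b`; quadratic and arbitrary functional
#' forms are supported for the improved Liu-type family (whose
#' SMSE-minimizing f is quadratic when the ridge estimator is plugged in).
#'
#' @param slope,intercept coefficients of the linear form `a k + b`.
#' @param form one of `"linear"`, `"fact2_line"`, `"quadratic"`, `"custom"`.
#'   Non-linear forms must supply `fun`.
#' @param provenance identifier recording which selection rule produced the
#'   line (e.g. `"g1"`, `"PRTE_I"`, `"user"`).
#' @param c integration constant of the `g1` family; required in (0, 1) when
#'   `provenance = "g1"`.
#' @param fun function of k for non-linear forms.
#' @return an object of class `gk_rule`.
#' @seealso [make_g_rule()] for the catalogue of data-driven rules.
#' @export
g_rule <- function(slope = NULL, intercept = NULL, form = "linear",
                   provenance = "user", c = NULL, fun = NULL) {
  form <- match.arg(form, c("linear", "fact2_line", "quadratic", "custom"))
  if (form %in% c("linear", "fact2_line")) {
    stopifnot(is.numeric(slope), is.numeric(intercept))
  } else if (is.null(fun)) {
    stop("non-linear rule forms require `fun`", call. = FALSE)
  }
  if (identical(provenance, "g1") && (is.null(c) || c <= 0 || c >= 1)) {
    stop("the g1 rule requires an integration constant c in (0, 1)", call. = FALSE)
  }
  structure(list(form = form, slope = slope, intercept = intercept,
                 c = c, provenance = provenance, fun = fun),
            class = "gk_rule")
}

#' Evaluate a biasing rule and its derivative
#'
#' @param rule a `gk_rule`.
#' @param k biasing parameter value(s), `k >= 0`.
#' @return `rule_value()` gives g(k); `rule_deriv()` gives g'(k) (exact for
#'   linear forms, central finite difference otherwise).
#' @export
rule_value <- function(rule, k) {
  stopifnot(inherits(rule, "gk_rule"))
  if (rule$form %in% c("linear", "fact2_line")) {
    rule$slope * k + rule$intercept
  } else {
    vapply(k, rule$fun, numeric(1))
  }
}

#' @rdname rule_value
#' @export
rule_deriv <- function(rule, k) {
  stopifnot(inherits(rule, "gk_rule"))
  if (rule$form %in% c("linear", "fact2_line")) {
    rep(rule$slope, length(k))
  } else {
    h <- 1e-6 * (1 + abs(k))
    (rule_value(rule, k + h) - rule_value(rule, k - h)) / (2 * h)
  }
}

#' @export
print.gk_rule <- function(x, ...) {
  if (x$form %in% c("linear", "fact2_line")) {
    cat(sprintf("gk_rule [%s]: g(k) = %.6g k + %.6g\n", x$provenance,
                x$slope, x$intercept))
  } else {
    cat(sprintf("gk_rule [%s]: %s form\n", x$provenance, x$form))
  }
  invisible(x)
}

shrinkage_families <- c("MLE", "PRE", "PLE", "PLTE", "PTPE", "PHY", "PSK",
                        "ILTE", "ILTE_PRE", "PRTE")

#' Specify a shrinkage estimator
#'
#' A `shrinkage_spec` names one of the estimator families for the Poisson
#' GLM and carries its biasing parameters. With `S = X'\hat W X` and
#' `b = \hat\beta_{MLE}` the families are
#' \describe{
#'   \item{MLE}{`b` (no shrinkage).}
#'   \item{PRE}{ridge, `(S + kI)^{-1} S b`.}
#'   \item{PLE}{Liu, `(S + I)^{-1}(S + dI) b`, `0 < d < 1`.}
#'   \item{PLTE}{Liu-type, `(S + kI)^{-1}(S - dI) b`, `d` real.}
#'   \item{PTPE}{two-parameter, `(S + kI)^{-1}(S + kdI) b`.}
#'   \item{PHY}{`(S + I)^{-1}(S + dI)` applied to the ridge estimator.}
#'   \item{PSK}{`(S + I)^{-1}(S + (k + d)I)` applied to the ridge estimator.}
#'   \item{ILTE}{`(S + kI)^{-1}(S + f(k)I) b*` with `b*` any base estimator
#'     (MLE by default).}
#'   \item{ILTE_PRE}{ILTE with the ridge estimator (same k) as base.}
#'   \item{PRTE}{ridge-type, `(S + I)^{-1}(S + g(k)I)` applied to the ridge
#'     estimator.}
#' }
#' The ridge-type family PRTE contains MLE (`k = 0`, `g(0) = 1`), PRE
#' (`g == 1`), PLE (`k = 0`, `g(0) = d`), PHY (`g == d` constant) and PSK
#' (`g(k) = k + d`) as special cases.
#'
#' Note that the intercept is shrunk along with the slopes: all matrix
#' formulas act on the full (p+1)-dimensional coefficient vector. Some ridge
#' traditions exempt the intercept; this implementation deliberately does
#' not.
#'
#' @param family one of `r paste0('"', shrinkage_families, '"', collapse = ", ")`.
#' @param k ridge biasing parameter, `k >= 0` (`k = 0` only as the
#'   documented no-shrinkage reduction).
#' @param d second biasing parameter where the family has one.
#' @param rule a [g_rule()] supplying f(k) (ILTE families) or g(k) (PRTE).
#' @param base optional nested `shrinkage_spec` used as the plug-in base
#'   estimator of the ILTE family.
#' @return an object of class `shrinkage_spec`.
#' @export
shrinkage_spec <- function(family, k = NULL, d = NULL, rule = NULL, base = NULL) {
  family <- match.arg(family, shrinkage_families)
  needs_k <- family %in% c("PRE", "PLTE", "PTPE", "PHY", "PSK", "ILTE",
                           "ILTE_PRE", "PRTE")
  if (needs_k) {
    if (is.null(k) || !is.finite(k) || k < 0) {
      stop(sprintf("family %s requires a biasing parameter k >= 0", family),
           call. = FALSE)
    }
  }
  if (family %in% c("PLE", "PTPE")) {
    if (is.null(d) || d < 0 || d > 1) {
      stop(sprintf("family %s requires d in [0, 1] (interior values for a proper %s; endpoints reduce to MLE/ridge)",
                   family, family), call. = FALSE)
    }
  }
  if (family == "PHY") {
    if (is.null(d)) stop("family PHY requires d", call. = FALSE)
    if (d <= 0 || d >= 1) {
      warning("PHY is defined for 0 < d < 1; value outside the admissible range",
              call. = FALSE)
    }
  }
  if (family %in% c("PLTE", "PSK") && is.null(d)) {
    stop(sprintf("family %s requires d", family), call. = FALSE)
  }
  if (family %in% c("ILTE", "ILTE_PRE", "PRTE") && is.null(rule)) {
    stop(sprintf("family %s requires a biasing rule (see g_rule())", family),
         call. = FALSE)
  }
  if (!is.null(base) && !inherits(base, "shrinkage_spec")) {
    stop("base must be a shrinkage_spec", call. = FALSE)
  }
  structure(list(family = family, k = k, d = d, rule = rule, base = base),
            class = "shrinkage_spec")
}

#' @export
print.shrinkage_spec <- function(x, ...) {
  cat(sprintf("shrinkage_spec: %s", x$family))
  if (!is.null(x$k)) cat(sprintf(", k = %.6g", x$k))
  if (!is.null(x$d)) cat(sprintf(", d = %.6g", x$d))
  if (!is.null(x$rule)) cat(sprintf(", rule = %s", x$rule$provenance))
  cat("\n")
  invisible(x)
}

#' Diagonal shrinkage factors of an estimator in canonical coordinates
#'
#' Every family maps the MLE linearly, `beta_hat = H beta_MLE`, and H is a
#' function of `X'\hat W X` alone, hence diagonal in the eigenbasis:
#' `H = Q diag(h_j) Q'`. This helper returns the factors `h_j` as a function
#' of the eigenvalues, and is the basis of both [induced_map()] and the risk
#' formulas.
#'
#' @param spec a `shrinkage_spec`.
#' @param lambda eigenvalues of the weighted information matrix.
#' @return numeric vector `h_j`, same length as `lambda`.
#' @export
shrink_factors <- function(spec, lambda) {
  stopifnot(inherits(spec, "shrinkage_spec"))
  k <- spec$k
  d <- spec$d
  switch(spec$family,
    MLE  = rep(1, length(lambda)),
    PRE  = lambda / (lambda + k),
    PLE  = (lambda + d) / (lambda + 1),
    PLTE = (lambda - d) / (lambda + k),
    PTPE = (lambda + k * d) / (lambda + k),
    PHY  = (lambda + d) * lambda / ((lambda + 1) * (lambda + k)),
    PSK  = (lambda + k + d) * lambda / ((lambda + 1) * (lambda + k)),
    ILTE = {
      base <- if (is.null(spec$base)) shrinkage_spec("MLE") else spec$base
      (lambda + rule_value(spec$rule, k)) / (lambda + k) *
        shrink_factors(base, lambda)
    },
    ILTE_PRE = (lambda + rule_value(spec$rule, k)) * lambda / (lambda + k)^2,
    PRTE = (lambda + rule_value(spec$rule, k)) * lambda /
      ((lambda + 1) * (lambda + k))
  )
}

#' The induced linear map H of a shrinkage estimator
#'
#' Returns the matrix H with `beta_hat = H beta_MLE`, reconstructed from the
#' canonical shrinkage factors: `H = Q diag(h_j) Q'`.
#'
#' @param spec a `shrinkage_spec`.
#' @param fit a converged `poisson_fit`, or a `canonical_form`.
#' @return a (p+1) x (p+1) matrix.
#' @export
induced_map <- function(spec, fit) {
  canon <- if (inherits(fit, "canonical_form")) fit else canonical_decompose(fit)
  h <- shrink_factors(spec, canon$lambda)
  canon$Q %*% (h * t(canon$Q))
}

pd_solve <- function(S, c, rhs) {
  # solve (S + c I) x = rhs through the Cholesky factor; S pd, c >= 0
  A <- S
  diag(A) <- diag(A) + c
  drop(chol2inv(chol(A)) %*% rhs)
}

#' Apply a shrinkage estimator to a fitted Poisson model
#'
#' Computes the family's matrix formula (see [shrinkage_spec()]) directly on
#' `X'\hat W X` and `beta_MLE` using symmetric positive definite solves; the
#' eigendecomposition route is exposed separately through [induced_map()] so
#' the two code paths can be cross-checked.
#'
#' @param spec a `shrinkage_spec`.
#' @param fit a converged `poisson_fit`.
#' @return the shrunken coefficient vector (length p+1, named like the
#'   design columns).
#' @examples
#' d <- count_dataset(matrix(rnorm(40), ncol = 2), y = rpois(20, 2))
#' fit <- fit_poisson_mle(d)
#' apply_shrinkage(shrinkage_spec("PRE", k = 0.5), fit)
#' @export
apply_shrinkage <- function(spec, fit) {
  stopifnot(inherits(spec, "shrinkage_spec"), inherits(fit, "poisson_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  S <- fit$xtwx
  b <- fit$beta_mle
  k <- spec$k
  d <- spec$d
  out <- switch(spec$family,
    MLE  = b,
    PRE  = pd_solve(S, k, S %*% b),
    PLE  = pd_solve(S, 1, S %*% b + d * b),
    PLTE = pd_solve(S, k, S %*% b - d * b),
    PTPE = pd_solve(S, k, S %*% b + k * d * b),
    PHY  = {
      b_pre <- pd_solve(S, k, S %*% b)
      pd_solve(S, 1, S %*% b_pre + d * b_pre)
    },
    PSK  = {
      b_pre <- pd_solve(S, k, S %*% b)
      pd_solve(S, 1, S %*% b_pre + (k + d) * b_pre)
    },
    ILTE = {
      base <- if (is.null(spec$base)) shrinkage_spec("MLE") else spec$base
      b_star <- apply_shrinkage(base, fit)
      f <- rule_value(spec$rule, k)
      pd_solve(S, k, S %*% b_star + f * b_star)
    },
    ILTE_PRE = {
      b_star <- pd_solve(S, k, S %*% b)
      f <- rule_value(spec$rule, k)
      pd_solve(S, k, S %*% b_star + f * b_star)
    },
    PRTE = {
      b_pre <- pd_solve(S, k, S %*% b)
      g <- rule_value(spec$rule, k)
      pd_solve(S, 1, S %*% b_pre + g * b_pre)
    }
  )
  stats::setNames(drop(out), names(b))
}

#' Improved Liu-type estimator
#'
#' Convenience wrapper: `(X'WX + kI)^{-1}(X'WX + f(k)I) b*` with `b*` the
#' base estimator (MLE by default, the ridge estimator for family
#' `"ILTE_PRE"`).
#'
#' @param spec a `shrinkage_spec` with family `"ILTE"` or `"ILTE_PRE"`.
#' @param fit a converged `poisson_fit`.
#' @return coefficient vector.
#' @export
ilte <- function(spec, fit) {
  if (!spec$family %in% c("ILTE", "ILTE_PRE")) {
    stop("ilte() expects a spec with family ILTE or ILTE_PRE", call. = FALSE)
  }
  apply_shrinkage(spec, fit)
}

#' Poisson ridge-type estimator
#'
#' Convenience wrapper for the ridge-type family:
#' `(X'WX + I)^{-1}(X'WX + g(k)I)` applied to the ridge estimator with the
#' same k. With a linear rule `g(k) = a k + b` the family reduces to the
#' ridge estimator (`g == 1`), the MLE (`k = 0`, `b = 1`), the PHY family
#' (`a = 0`, `b = d`) and the PSK family (`a = 1`, `b = d`).
#'
#' @param spec a `shrinkage_spec` with family `"PRTE"`.
#' @param fit a converged `poisson_fit`.
#' @return coefficient vector.
#' @export
prte <- function(spec, fit) {
  if (!identical(spec$family, "PRTE")) {
    stop("prte() expects a spec with family PRTE", call. = FALSE)
  }
  apply_shrinkage(spec, fit)
}
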