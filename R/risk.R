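#' Positive-definiteness check by smallest eigenvalue
#'
#' A symmetric matrix is declared positive definite when the smallest
#' eigenvalue of its symmetrized form exceeds `tolerance` (default 1e-12);
#' any eigenvalue at or below the tolerance fails the check.
#'
#' @param m square matrix.
#' @param tolerance eigenvalue threshold.
#' @return logical.
#' @export
is_pd <- function(m, tolerance = 1e-12) {
  m <- as.matrix(m)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tolerance
}

#' Asymptotic matrix mean squared error of a shrinkage estimator
#'
#' For an estimator `beta_hat = H beta_MLE` the asymptotic MMSE is
#' \deqn{MMSE = H \, Cov(\hat\beta_{MLE}) \, H' + (H - I)\beta\beta'(H - I)'}
#' with `Cov = (X'WX)^{-1}`. Since every family's H is diagonal in the
#' eigenbasis, the MMSE is evaluated in canonical coordinates as
#' `diag(h_j^2/lambda_j) + b b'` with bias vector `b_j = (h_j - 1) alpha_j`,
#' then rotated back by Q on request.
#'
#' @param spec a `shrinkage_spec` (any family).
#' @param canon a `canonical_form`.
#' @param alpha the true canonical coefficient vector; defaults to the
#'   plug-in `canon$alpha` (flag `truth_plugin` in the report records this).
#' @param rotate rotate the MMSE and bias back to the original coordinates
#'   (default `TRUE`); `FALSE` keeps canonical coordinates.
#' @return an object of class `risk_report` with elements `estimator`,
#'   `mmse`, `smse`, `variance_part`, `bias_sq_part`, `bias_vector`,
#'   `truth_plugin`.
#' @export
mmse_matrix <- function(spec, canon, alpha = NULL, rotate = TRUE) {
  stopifnot(inherits(spec, "shrinkage_spec"), inherits(canon, "canonical_form"))
  plugin <- is.null(alpha)
  if (plugin) alpha <- canon$alpha
  if (length(alpha) != length(canon$lambda)) {
    stop("alpha must match the number of canonical components", call. = FALSE)
  }
  h <- shrink_factors(spec, canon$lambda)
  b <- (h - 1) * alpha
  mm <- diag(h^2 / canon$lambda, nrow = length(h)) + tcrossprod(b)
  bias <- b
  if (rotate) {
    mm <- canon$Q %*% mm %*% t(canon$Q)
    bias <- drop(canon$Q %*% b)
  }
  structure(
    list(estimator = spec, mmse = mm,
         smse = sum(h^2 / canon$lambda) + sum(b^2),
         variance_part = sum(h^2 / canon$lambda),
         bias_sq_part = sum(b^2),
         bias_vector = bias,
         truth_plugin = plugin),
    class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("risk_report [%s]: SMSE = %.6g (variance %.6g + bias^2 %.6g)%s\n",
              x$estimator$family, x$smse, x$variance_part, x$bias_sq_part,
              if (x$truth_plugin) "  [plug-in truth]" else ""))
  invisible(x)
}

#' Asymptotic scalar mean squared error
#'
#' The scalar risk `SMSE = trace(MMSE)`. For the improved Liu-type and
#' ridge-type families the closed-form diagonal sums are evaluated directly:
#' \deqn{SMSE_{ILTE} = \sum_j \frac{(\lambda_j + f)^2}{\lambda_j(\lambda_j+k)^2}
#'   + \sum_j \frac{(f-k)^2 \alpha_j^2}{(\lambda_j+k)^2}}
#' \deqn{SMSE_{ILTE(PRE)} = \sum_j \frac{(\lambda_j+f)^2\lambda_j}{(\lambda_j+k)^4}
#'   + \sum_j \frac{(f\lambda_j - 2k\lambda_j - k^2)^2 \alpha_j^2}{(\lambda_j+k)^4}}
#' \deqn{SMSE_{PRTE} = \sum_j \frac{\lambda_j(\lambda_j+g)^2}
#'   {(\lambda_j+1)^2(\lambda_j+k)^2}
#'   + \sum_j \frac{((g-k-1)\lambda_j - k)^2 \alpha_j^2}
#'   {(\lambda_j+1)^2(\lambda_j+k)^2}}
#' where the first terms are the asymptotic variance and the second the
#' squared bias. Other families use the generic `sum(h_j^2/lambda_j) +
#' sum((h_j - 1)^2 alpha_j^2)`.
#'
#' @inheritParams mmse_matrix
#' @return scalar risk value.
#' @export
smse <- function(spec, canon, alpha = NULL) {
  stopifnot(inherits(spec, "shrinkage_spec"), inherits(canon, "canonical_form"))
  if (is.null(alpha)) alpha <- canon$alpha
  lam <- canon$lambda
  a2 <- alpha^2
  k <- spec$k
  if (spec$family == "ILTE" && is.null(spec$base)) {
    f <- rule_value(spec$rule, k)
    return(sum((lam + f)^2 / (lam * (lam + k)^2)) +
             sum((f - k)^2 * a2 / (lam + k)^2))
  }
  if (spec$family == "ILTE_PRE") {
    f <- rule_value(spec$rule, k)
    return(sum((lam + f)^2 * lam / (lam + k)^4) +
             sum((f * lam - 2 * k * lam - k^2)^2 * a2 / (lam + k)^4))
  }
  if (spec$family == "PRTE") {
    g <- rule_value(spec$rule, k)
    return(sum(lam * (lam + g)^2 / ((lam + 1)^2 * (lam + k)^2)) +
             sum(((g - k - 1) * lam - k)^2 * a2 / ((lam + 1)^2 * (lam + k)^2)))
  }
  h <- shrink_factors(spec, lam)
  sum(h^2 / lam) + sum((h - 1)^2 * a2)
}

#' Derivative of the ridge-type SMSE in the biasing parameter
#'
#' Writing `h(k) = SMSE(PRTE)` for a given biasing function g, the
#' derivative is
#' \deqn{h'(k) = \sum_j \frac{2\lambda_j(\lambda_j - g'\lambda_j - g'k + g)
#'   \left[\alpha_j^2((k + 1 - g)\lambda_j + k) - (\lambda_j + g)\right]}
#'   {(\lambda_j + 1)^2 (\lambda_j + k)^3}.}
#' The stationarity condition `h'(k) = 0` factorizes: the first factor
#' vanishes on the lines `g(k) = ck + (c-1)lambda_j` (any constant c), the
#' second on the line with slope
#' `alpha_j^2(lambda_j + 1)/(1 + lambda_j alpha_j^2)` — the two families of
#' linear rules behind [make_g_rule()].
#'
#' @param g_rule a [g_rule()].
#' @param canon a `canonical_form`.
#' @param alpha true canonical coefficients (default plug-in `canon$alpha`).
#' @param k evaluation point(s), `k > 0`.
#' @return the derivative value(s).
#' @export
smse_derivative <- function(g_rule, canon, alpha = NULL, k) {
  stopifnot(inherits(g_rule, "gk_rule"), inherits(canon, "canonical_form"))
  if (is.null(alpha)) alpha <- canon$alpha
  lam <- canon$lambda
  a2 <- alpha^2
  vapply(k, function(kk) {
    g <- rule_value(g_rule, kk)
    gp <- rule_deriv(g_rule, kk)
    sum(2 * lam * (lam - gp * lam - gp * kk + g) *
          (a2 * ((kk + 1 - g) * lam + kk) - (lam + g)) /
          ((lam + 1)^2 * (lam + kk)^3))
  }, numeric(1))
}

#' Superiority of the ridge-type estimator over the improved Liu-type
#'
#' Evaluates, for a given k and pair of biasing functions, whether
#' `MMSE(ILTE) - MMSE(PRTE)` is positive definite. The check follows the
#' matrix-difference decomposition `Q (D - b b') Q'` with
#' \deqn{D_j = \frac{(\lambda_j + f)^2}{\lambda_j(\lambda_j + k)^2} -
#'   \frac{\lambda_j (\lambda_j + g)^2}{(\lambda_j+1)^2 (\lambda_j+k)^2}}
#' and the PRTE bias `b_j = ((g - k - 1)\lambda_j - k)\alpha_j /
#' ((\lambda_j+1)(\lambda_j+k))`. D is positive definite exactly when g(k)
#' lies, for every component, inside the interval
#' \deqn{-\lambda_j - \frac{(\lambda_j+1)(\lambda_j+f)}{\lambda_j} < g(k) <
#'   -\lambda_j + \frac{(\lambda_j+1)(\lambda_j+f)}{\lambda_j},}
#' and then the difference is positive definite iff the quadratic form
#' `b' D^{-1} b < 1`. The report also carries a direct eigenvalue check of
#' the assembled difference, so the interval/quadratic-form verdict can be
#' validated against it.
#'
#' @param f_rule,g_rule [g_rule()] objects supplying f(k) and g(k).
#' @param canon a `canonical_form`.
#' @param alpha true canonical coefficients (default plug-in `canon$alpha`).
#' @param k biasing parameter, `k > 0`.
#' @param tolerance positive-definiteness tolerance (default 1e-12). When D
#'   is numerically singular the quadratic form is reported as `NA`
#'   (indeterminate) rather than an error.
#' @return an object of class `theorem_report` with fields `k`, `f_rule`,
#'   `g_rule`, `interval_ok`, `d_matrix_pd`, `condition22_value`,
#'   `condition22_ok`, `mmse_difference_pd`, `tolerance`.
#' @export
prte_superiority <- function(f_rule, g_rule, canon, alpha = NULL, k,
                             tolerance = 1e-12) {
  stopifnot(inherits(f_rule, "gk_rule"), inherits(g_rule, "gk_rule"),
            inherits(canon, "canonical_form"), k > 0)
  if (is.null(alpha)) alpha <- canon$alpha
  lam <- canon$lambda
  f <- rule_value(f_rule, k)
  g <- rule_value(g_rule, k)
  half_width <- (lam + 1) * (lam + f) / lam
  interval_ok <- all(-lam - half_width < g & g < -lam + half_width)
  dj <- (lam + f)^2 / (lam * (lam + k)^2) -
    lam * (lam + g)^2 / ((lam + 1)^2 * (lam + k)^2)
  d_matrix_pd <- all(dj > tolerance)
  bias <- ((g - k - 1) * lam - k) * alpha / ((lam + 1) * (lam + k))
  if (any(abs(dj) <= tolerance)) {
    cond_value <- NA_real_
    cond_ok <- NA
  } else {
    cond_value <- sum(bias^2 / dj)
    cond_ok <- d_matrix_pd && cond_value < 1
  }
  diff_canon <- diag(dj, nrow = length(dj)) - tcrossprod(bias)
  structure(
    list(k = k, f_rule = f_rule, g_rule = g_rule,
         interval_ok = interval_ok, d_matrix_pd = d_matrix_pd,
         condition22_value = cond_value, condition22_ok = cond_ok,
         mmse_difference_pd = is_pd(diff_canon, tolerance),
         tolerance = tolerance),
    class = "theorem_report")
}

#' @export
print.theorem_report <- function(x, ...) {
  cat(sprintf("theorem_report at k = %.4g:\n", x$k))
  cat(sprintf("  g(k) within interval bounds: %s\n", x$interval_ok))
  cat(sprintf("  D matrix pd: %s\n", x$d_matrix_pd))
  cat(sprintf("  quadratic form: %s (< 1: %s)\n",
              format(x$condition22_value, digits = 6), x$condition22_ok))
  cat(sprintf("  MMSE(ILTE) - MMSE(PRTE) pd: %s\n", x$mmse_difference_pd))
  invisible(x)
}

#' Risk sweep over a grid of biasing parameter values
#'
#' Tabulates the asymptotic variance and SMSE of the k-sweep estimator
#' triplet (improved Liu-type on the MLE, on the ridge estimator, and the
#' ridge-type estimator) over a grid of k values, suitable for CSV export
#' and plotting.
#'
#' @param canon a `canonical_form`.
#' @param alpha true canonical coefficients (default plug-in `canon$alpha`).
#' @param rules named list with elements `f_ilte`, `f_ilte_pre`, `g_prte`
#'   (default: [sweep_rules()] on the plug-in biasing inputs).
#' @param k_grid grid of k values (default 0 to 2 in steps of 0.1).
#' @return a data frame with columns `k`, `estimator`, `variance`, `smse`.
#' @export
smse_sweep <- function(canon, alpha = NULL,
                       rules = sweep_rules(biasing_inputs(canon)),
                       k_grid = seq(0, 2, by = 0.1)) {
  stopifnot(inherits(canon, "canonical_form"))
  if (is.null(alpha)) alpha <- canon$alpha
  fam <- c(ILTE = "f_ilte", ILTE_PRE = "f_ilte_pre", PRTE = "g_prte")
  out <- lapply(names(fam), function(family) {
    rule <- rules[[fam[[family]]]]
    rows <- lapply(k_grid, function(k) {
      spec <- shrinkage_spec(family, k = k, rule = rule)
      rep <- mmse_matrix(spec, canon, alpha, rotate = FALSE)
      data.frame(k = k, estimator = family,
                 variance = rep$variance_part, smse = rep$smse)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}
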