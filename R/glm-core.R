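#' Fit a Poisson regression model by iteratively reweighted least squares
#'
#' Maximizes the Poisson log-likelihood
#' \deqn{l(\beta) = \sum_i y_i x_i'\beta - \exp(x_i'\beta) - \log(y_i!)}
#' under the canonical log link by Fisher scoring, i.e. the IRLS update
#' \deqn{\beta \leftarrow (X'\hat W X)^{-1} X'\hat W Z}
#' with weights \eqn{\hat W = \mathrm{diag}(\hat\mu_i)} and working response
#' \eqn{z_i = \log\hat\mu_i + (y_i - \hat\mu_i)/\hat\mu_i}. The iteration is
#' started from a least-squares regression of \eqn{\log(y + 0.5)} on the
#' design and stops when the largest absolute coefficient change falls below
#' `tolerance`. If an update would decrease the log-likelihood the step is
#' halved (at most 10 times per iteration).
#'
#' The returned object also carries the residual variance
#' \eqn{\hat\sigma^2 = \sum_i (y_i - \hat\mu_i)^2 / (n - p - 1)} used by the
#' biasing-parameter rules, where p is the number of covariates.
#'
#' @param data a `count_dataset` with a response; the design must have full
#'   column rank.
#' @param tolerance convergence threshold on the maximum absolute
#'   coefficient change (default `1e-8`).
#' @param max_iterations iteration cap; exceeding it returns a fit flagged
#'   `converged = FALSE` (never a silent success).
#' @return An object of class `poisson_fit` with elements `beta_mle`,
#'   `mu_hat`, `weight_diag`, `working_response`, `xtwx`, `cov_mle`,
#'   `converged`, `iterations`, `loglik`, `sigma2_hat`, `n`, `p`, and the
#'   originating `data`.
#' @examples
#' d <- count_dataset(matrix(c(0.1, -0.2, 0.4, 0.3, -0.1, 0.2), ncol = 2),
#'                    y = c(1, 2, 0))
#' fit <- fit_poisson_mle(d)
#' coef(fit)
#' @export
fit_poisson_mle <- function(data, tolerance = 1e-8, max_iterations = 100L) {
  stopifnot(inherits(data, "count_dataset"))
  validate_count_dataset(data, need_response = TRUE)
  X <- data$design
  y <- data$response
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop(sprintf("design matrix is rank deficient (rank %d < %d columns)",
                 qrX$rank, ncol(X)), call. = FALSE)
  }

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - exp(eta)) - sum(lfactorial(y))
  }

  beta <- qr.coef(qrX, log(y + 0.5))
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    xtwx <- crossprod(X, X * mu)
    xtwz <- crossprod(X, mu * z)
    beta_new <- drop(solve(xtwx, xtwz))
    # step-halving keeps the likelihood ascent monotone on hard starts
    step <- beta_new - beta
    ll_new <- loglik(beta_new)
    halvings <- 0L
    while (!is.finite(ll_new) || ll_new < ll - 1e-12) {
      if (halvings >= 10L) break
      halvings <- halvings + 1L
      step <- step / 2
      beta_new <- beta + step
      ll_new <- loglik(beta_new)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- ll_new
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
    if (iter >= max_iterations) break
  }

  eta <- drop(X %*% beta)
  mu <- exp(eta)
  z <- eta + (y - mu) / mu
  xtwx <- crossprod(X, X * mu)
  xtwx <- (xtwx + t(xtwx)) / 2
  cov_mle <- chol2inv(chol(xtwx))
  p <- n_covariates(data)
  sigma2 <- sum((y - mu)^2) / (n - p - 1)
  names(beta) <- colnames(X)

  structure(
    list(beta_mle = beta, mu_hat = mu, weight_diag = mu,
         working_response = z, xtwx = xtwx, cov_mle = cov_mle,
         converged = converged, iterations = iter, loglik = ll,
         sigma2_hat = sigma2, n = n, p = p, data = data),
    class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("Poisson GLM fit (IRLS): n = %d, p = %d, %s in %d iteration(s)\n",
              x$n, x$p,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("Coefficients:\n")
  print(round(x$beta_mle, 4))
  cat(sprintf("log-likelihood: %.4f   sigma2_hat: %.4f\n", x$loglik, x$sigma2_hat))
  invisible(x)
}

#' @export
coef.poisson_fit <- function(object, ...) object$beta_mle

#' @export
logLik.poisson_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta_mle), class = "logLik")
}

#' Eigendecomposition of the weighted information matrix
#'
#' Decomposes \eqn{X'\hat W X = Q \Lambda Q'} with eigenvalues sorted in
#' decreasing order and computes the canonical coefficients
#' \eqn{\hat\alpha = Q'\hat\beta_{MLE}}. All risk formulas and biasing rules
#' are diagonal in this rotated coordinate system. Eigenvector signs are
#' fixed so that the first non-zero entry of each column is positive.
#'
#' @param fit a converged `poisson_fit`.
#' @return an object of class `canonical_form`; see [canonical_form()].
#' @export
canonical_decompose <- function(fit) {
  stopifnot(inherits(fit, "poisson_fit"))
  if (!fit$converged) stop("fit did not converge; refusing to decompose", call. = FALSE)
  e <- eigen(fit$xtwx, symmetric = TRUE)
  if (any(e$values <= 0)) {
    stop("weighted information matrix is numerically not positive definite", call. = FALSE)
  }
  Q <- fix_eigvec_signs(e$vectors)
  canonical_form(lambda = e$values, Q = Q,
                 alpha = drop(crossprod(Q, fit$beta_mle)),
                 n = fit$n, p = fit$p, sigma2 = fit$sigma2_hat)
}

fix_eigvec_signs <- function(Q) {
  for (j in seq_len(ncol(Q))) {
    nz <- which(abs(Q[, j]) > 1e-12)[1]
    if (!is.na(nz) && Q[nz, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

#' Canonical form of a (weighted) information matrix
#'
#' Container for the eigenvalues `lambda` (decreasing), eigenvector matrix
#' `Q` and canonical coefficients `alpha` of an information matrix, together
#' with the summary statistics used by the biasing-parameter rules. Usually
#' produced by [canonical_decompose()]; the constructor is exported so that
#' theoretical risk studies can be run on synthetic (`lambda`, `alpha`)
#' configurations without an underlying dataset.
#'
#' @param lambda positive eigenvalues in decreasing order.
#' @param Q orthogonal eigenvector matrix (columns match `lambda`); defaults
#'   to the identity.
#' @param alpha canonical coefficient vector (same length as `lambda`).
#' @param n,p sample size and number of covariates (used by rules with n or
#'   p factors); default `p = length(lambda) - 1`.
#' @param sigma2 residual variance estimate, if available.
#' @return an object of class `canonical_form` with the fields above plus
#'   `summaries` (`lambda_min`, `lambda_max`, `alpha2_min`, `alpha2_max`,
#'   `alpha2_med`, `alpha2_mean`).
#' @export
canonical_form <- function(lambda, Q = diag(length(lambda)), alpha,
                           n = NULL, p = length(lambda) - 1L, sigma2 = NULL) {
  lambda <- as.numeric(lambda)
  alpha <- as.numeric(alpha)
  stopifnot(length(alpha) == length(lambda), all(lambda > 0))
  if (is.unsorted(rev(lambda))) stop("eigenvalues must be in decreasing order", call. = FALSE)
  a2 <- alpha^2
  structure(
    list(lambda = lambda, Q = Q, alpha = alpha, n = n, p = p, sigma2 = sigma2,
         summaries = list(lambda_min = min(lambda), lambda_max = max(lambda),
                          alpha2_min = min(a2), alpha2_max = max(a2),
                          alpha2_med = stats::median(a2), alpha2_mean = mean(a2))),
    class = "canonical_form")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat(sprintf("canonical_form: %d component(s)\n", length(x$lambda)))
  cat("lambda:", paste(format(x$lambda, digits = 6), collapse = ", "), "\n")
  cat("alpha :", paste(format(x$alpha, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Condition number of a symmetric positive definite matrix
#'
#' Returns the ratio of the largest to the smallest eigenvalue,
#' \eqn{\lambda_{max}/\lambda_{min}}. Values above about 30 are the usual
#' diagnostic for a multicollinearity problem in the information matrix.
#'
#' @param m symmetric positive definite matrix.
#' @return a single number, \eqn{\ge 1}.
#' @export
condition_number <- function(m) {
  m <- as.matrix(m)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("matrix must be positive definite", call. = FALSE)
  max(ev) / min(ev)
}

#' Serialize a fit's headline quantities to JSON
#'
#' @param fit a `poisson_fit`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "poisson_fit"))
  canon <- canonical_decompose(fit)
  out <- list(coefficients = as.list(fit$beta_mle),
              eigenvalues = canon$lambda,
              condition_number = max(canon$lambda) / min(canon$lambda),
              sigma2_hat = fit$sigma2_hat,
              loglik = fit$loglik,
              converged = fit$converged,
              iterations = fit$iterations)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
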