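# Shared fixture builders: everything is generated in code at test time.

# Small fixed design with a response, deterministic for a seed.
toy_dataset <- function(seed = 42, n = 25, p = 2, intercept = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p, sd = 0.5), n, p)
  beta <- c(if (intercept) 0.3 else NULL, seq_len(p) / (2 * p))
  design <- if (intercept) cbind(1, x) else x
  y <- rpois(n, exp(drop(design %*% beta)))
  count_dataset(x, y, add_intercept = intercept)
}

# Minimal object standing in for a converged fit with prescribed
# information matrix and MLE vector; enough for the estimator algebra.
fake_fit <- function(S, beta) {
  S <- (S + t(S)) / 2
  structure(
    list(beta_mle = as.numeric(beta), xtwx = S,
         cov_mle = chol2inv(chol(S)), converged = TRUE,
         mu_hat = NULL, n = nrow(S) * 10L, p = nrow(S) - 1L,
         sigma2_hat = 1),
    class = "poisson_fit")
}

# Random symmetric positive definite matrix with moderate conditioning.
random_pd <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(m * m), m, m)
  crossprod(A) + diag(m) * 0.5
}

# Random canonical configuration for risk-formula tests.
random_canon <- function(m = 3, seed = NULL, n = 50) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- sort(exp(rnorm(m, 0.5, 1)), decreasing = TRUE)
  alpha <- rnorm(m)
  canonical_form(lambda = lambda, alpha = alpha, n = n, p = m - 1L,
                 sigma2 = exp(rnorm(1, 0, 0.3)))
}

random_linear_rule <- function(seed = NULL, lambda_min = 1) {
  if (!is.null(seed)) set.seed(seed)
  slope <- runif(1, 0, 1.5)
  g_rule(slope = slope, intercept = (slope - 1) * lambda_min)
}
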