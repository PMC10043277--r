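#' Generate a collinear design matrix
#'
#' Covariates are built from independent standard normal draws `w` as
#' \deqn{x_{ij} = (1 - \rho^2)^{1/2} w_{ij} + \rho w_{i,p+1},}
#' so that any two covariates have correlation `rho^2` in expectation; `rho`
#' close to 1 produces the high-multicollinearity regimes the shrinkage
#' estimators are designed for. By default the covariate columns are
#' centred and scaled to unit length (see [standardize_dataset()]); under
#' that convention the collinearity level, not the sample size, drives the
#' conditioning of the information matrix.
#'
#' The simulated model is the p-dimensional model without an intercept (the
#' intercept coefficient of the generating process is zero and the fitted
#' model omits the term), so that the dominant eigenvalue of the
#' information matrix belongs to the signal direction the biasing rules are
#' designed around; set `intercept = TRUE` to append a column of ones
#' instead.
#'
#' @param n sample size.
#' @param p number of covariates.
#' @param rho collinearity level in [0, 1).
#' @param seed optional seed for reproducibility (same seed, same design).
#' @param standardize centre/scale covariate columns to unit length
#'   (default `TRUE`).
#' @param intercept append an intercept column (default `FALSE`).
#' @return a design-only `count_dataset` (response `NULL`).
#' @export
generate_design <- function(n, p, rho, seed = NULL, standardize = TRUE,
                            intercept = FALSE) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(stats::rnorm(n * (p + 1)), n, p + 1)
  x <- sqrt(1 - rho^2) * w[, seq_len(p), drop = FALSE] + rho * w[, p + 1]
  data <- count_dataset(x, y = NULL, add_intercept = intercept)
  if (standardize) data <- standardize_dataset(data)
  data
}

#' True coefficient vector for a simulated design
#'
#' The slope block is the unit-norm eigenvector of `X'X` (covariates only)
#' associated with the largest eigenvalue, so `beta'beta = 1` and the signal
#' is aligned with the dominant axis of the design — the configuration in
#' which collinearity damage to the MLE is maximal. The sign is fixed (first
#' non-zero entry positive) and the intercept coefficient is set to 0.
#'
#' @param data a `count_dataset` (design-only is fine).
#' @return coefficient vector of length p+1 (with intercept) or p.
#' @export
true_beta <- function(data) {
  stopifnot(inherits(data, "count_dataset"))
  x <- data$design[, covariate_columns(data), drop = FALSE]
  e <- eigen(crossprod(x), symmetric = TRUE)
  v <- fix_eigvec_signs(e$vectors[, 1, drop = FALSE])[, 1]
  v <- v / sqrt(sum(v^2))
  if (data$include_intercept) c(0, v) else v
}

#' Names of the registered plug-in estimators
#'
#' The estimator set used by [run_scenario()] and [bootstrap_smse()]:
#' the MLE; the ridge estimator with the maximum rule; the Liu estimator
#' with the clipped minimum rule; three Liu-type (k, d) pairings; the two
#' default PHY strategies; the PSK estimator; and the four ridge-type
#' rule/k pairings (see [estimate_k()], [estimate_d()], [make_g_rule()],
#' [phy_strategy()]).
#'
#' @return character vector of estimator names.
#' @export
default_estimator_set <- function() {
  c("MLE", "PRE", "PLE", "PLTE_I", "PLTE_II", "PLTE_III",
    "PHY_I", "PHY_II", "PSK", "PRTE_I", "PRTE_II", "PRTE_III", "PRTE_IV")
}

#' Resolve a named estimator to a concrete shrinkage specification
#'
#' Pairs each catalogue name with its biasing-parameter rules, evaluated on
#' the supplied inputs (plug-in eigenvalues, canonical coefficients and
#' residual variance of a fitted model).
#'
#' @param name an element of [default_estimator_set()].
#' @param inputs a `biasing_inputs` object.
#' @return a `shrinkage_spec` with numeric biasing parameters.
#' @export
resolve_estimator <- function(name, inputs) {
  stopifnot(inherits(inputs, "biasing_inputs"))
  switch(name,
    MLE = shrinkage_spec("MLE"),
    PRE = shrinkage_spec("PRE", k = estimate_k("k_PRE_kibria", inputs)),
    PLE = shrinkage_spec("PLE", d = estimate_d("d_PLE_qasim", inputs)),
    PLTE_I = {
      k <- estimate_k("k_PLTE_I", inputs)
      shrinkage_spec("PLTE", k = k, d = estimate_d("d_PLTE_ratio", inputs, k))
    },
    PLTE_II = {
      k <- estimate_k("k_PLTE_II", inputs)
      shrinkage_spec("PLTE", k = k, d = estimate_d("d_PLTE_ratio", inputs, k))
    },
    PLTE_III = {
      shrinkage_spec("PLTE", k = estimate_k("k_PLTE_III", inputs),
                     d = estimate_d("d_PLTE_halfmin", inputs))
    },
    PHY_I = {
      kd <- phy_strategy("HK")(inputs)
      shrinkage_spec("PHY", k = kd$k, d = kd$d)
    },
    PHY_II = {
      kd <- phy_strategy("HKB")(inputs)
      shrinkage_spec("PHY", k = kd$k, d = kd$d)
    },
    PSK = {
      k <- estimate_k("k_PSK", inputs)
      shrinkage_spec("PSK", k = k, d = estimate_d("d_PSK", inputs, k))
    },
    PRTE_I = shrinkage_spec("PRTE", k = estimate_k("k_PRTE_I", inputs),
                            rule = make_g_rule("PRTE_I", inputs)),
    PRTE_II = shrinkage_spec("PRTE", k = estimate_k("k_PRTE_II", inputs),
                             rule = make_g_rule("PRTE_II", inputs)),
    PRTE_III = shrinkage_spec("PRTE", k = estimate_k("k_PRTE_III", inputs),
                              rule = make_g_rule("PRTE_III", inputs)),
    PRTE_IV = shrinkage_spec("PRTE", k = estimate_k("k_PRTE_IV", inputs),
                             rule = make_g_rule("PRTE_IV", inputs)),
    stop(sprintf("unknown estimator '%s'; available: %s", name,
                 paste(default_estimator_set(), collapse = ", ")),
         call. = FALSE)
  )
}

#' Run a replicated Monte Carlo estimation scenario
#'
#' Draws one collinear design for the scenario (held fixed across
#' replications), sets the true coefficient vector via [true_beta()], and
#' for each replication regenerates Poisson responses
#' `y_i ~ Poisson(exp(x_i' beta))`, fits the MLE, evaluates the configured
#' estimators with their plug-in biasing rules, and accumulates squared
#' estimation errors. The reported criterion is the estimated MSE,
#' \deqn{EMSE(\hat\beta) = \frac{1}{N}\sum_{r=1}^{N}
#'   (\hat\beta_r - \beta)'(\hat\beta_r - \beta).}
#'
#' In `k_grid` mode the estimator set is replaced by the sweep triplet of
#' [sweep_rules()] (improved Liu-type on MLE and on the ridge estimator,
#' and the ridge-type estimator), evaluated at every grid value of k within
#' each replication; `emse` is then a matrix (grid x estimator).
#'
#' Replications whose IRLS fit fails or does not converge are dropped and
#' counted (`n_fail`), never imputed; a scenario with more than 10% failures
#' is flagged. Per-replication seeds are derived deterministically from
#' `seed`, so a dropped replication does not shift later draws.
#'
#' @param n,p,rho scenario dimensions and collinearity level.
#' @param n_rep number of replications (default 2000).
#' @param seed master seed.
#' @param estimators character vector of estimator names
#'   (see [default_estimator_set()]).
#' @param k_grid optional grid of k values switching to sweep mode.
#' @param fresh_design draw a fresh design each replication instead of
#'   holding X fixed (default `FALSE`).
#' @param standardize standardize the design columns (default `TRUE`).
#' @param intercept include an intercept column in the simulated model
#'   (default `FALSE`; see [generate_design()]).
#' @param response_sampler response generator `function(mu)`; defaults to
#'   Poisson sampling (overridable hook for deterministic tests).
#' @return an object of class `simulation_result` with elements `emse`,
#'   `n_rep`, `n_fail`, `flagged`, `beta`, `eigen_summary` (eigenvalues of
#'   the expected information at the true coefficients), `config`.
#' @export
run_scenario <- function(n, p, rho, n_rep = 2000L, seed = 1L,
                         estimators = default_estimator_set(),
                         k_grid = NULL, fresh_design = FALSE,
                         standardize = TRUE, intercept = FALSE,
                         response_sampler = NULL) {
  stopifnot(n_rep >= 1)
  data <- generate_design(n, p, rho, seed = seed, standardize = standardize,
                          intercept = intercept)
  beta <- true_beta(data)
  mu <- exp(drop(data$design %*% beta))
  if (is.null(response_sampler)) {
    response_sampler <- function(mu) stats::rpois(length(mu), mu)
  }
  sweep_mode <- !is.null(k_grid)
  if (sweep_mode) {
    sweep_names <- c("ILTE", "ILTE_PRE", "PRTE")
    sse <- matrix(0, length(k_grid), length(sweep_names),
                  dimnames = list(format(k_grid), sweep_names))
  } else {
    sse <- stats::setNames(numeric(length(estimators)), estimators)
  }
  n_fail <- 0L
  n_ok <- 0L

  for (r in seq_len(n_rep)) {
    set.seed(seed + r)
    d_r <- data
    beta_r <- beta
    if (fresh_design) {
      d_r <- generate_design(n, p, rho, seed = NULL, standardize = standardize,
                             intercept = intercept)
      beta_r <- true_beta(d_r)
    }
    d_r$response <- response_sampler(if (fresh_design)
      exp(drop(d_r$design %*% beta_r)) else mu)
    fit <- tryCatch(fit_poisson_mle(d_r), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_fail <- n_fail + 1L
      next
    }
    canon <- tryCatch(canonical_decompose(fit), error = function(e) NULL)
    if (is.null(canon)) {
      n_fail <- n_fail + 1L
      next
    }
    inputs <- biasing_inputs(fit, canon)
    alpha_hat <- canon$alpha
    if (sweep_mode) {
      rules <- sweep_rules(inputs)
      lam <- canon$lambda
      for (i in seq_along(k_grid)) {
        k <- k_grid[i]
        f1 <- rule_value(rules$f_ilte, k)
        f2 <- rule_value(rules$f_ilte_pre, k)
        g <- rule_value(rules$g_prte, k)
        hs <- cbind(
          ILTE = (lam + f1) / (lam + k),
          ILTE_PRE = (lam + f2) * lam / (lam + k)^2,
          PRTE = (lam + g) * lam / ((lam + 1) * (lam + k)))
        for (s in seq_along(sweep_names)) {
          coef_s <- drop(canon$Q %*% (hs[, s] * alpha_hat))
          sse[i, s] <- sse[i, s] + sum((coef_s - beta_r)^2)
        }
      }
    } else {
      for (nm in estimators) {
        spec <- suppressWarnings(resolve_estimator(nm, inputs))
        h <- shrink_factors(spec, canon$lambda)
        coef_e <- drop(canon$Q %*% (h * alpha_hat))
        sse[nm] <- sse[nm] + sum((coef_e - beta_r)^2)
      }
    }
    n_ok <- n_ok + 1L
  }

  if (n_ok == 0L) stop("every replication failed to converge", call. = FALSE)
  lam_true <- eigen(crossprod(data$design, data$design * mu),
                    symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(emse = sse / n_ok, n_rep = n_rep, n_fail = n_fail,
         flagged = n_fail > 0.1 * n_rep, beta = beta,
         eigen_summary = lam_true,
         config = list(n = n, p = p, rho = rho, seed = seed,
                       standardize = standardize,
                       fresh_design = fresh_design, k_grid = k_grid)),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("simulation_result: n = %d, p = %d, rho = %.3f, %d replication(s), %d failed%s\n",
              cfg$n, cfg$p, cfg$rho, x$n_rep, x$n_fail,
              if (x$flagged) " [FLAGGED: >10% failures]" else ""))
  if (is.matrix(x$emse)) {
    cat("EMSE by k (rows) and estimator (columns):\n")
    print(round(x$emse, 4))
  } else {
    cat("EMSE:\n")
    print(round(x$emse, 4))
  }
  invisible(x)
}

#' Tabulate EMSE values over a grid of scenarios
#'
#' Runs [run_scenario()] for each row of `scenarios` and assembles the
#' results in a wide table (one row per scenario, one column per estimator)
#' together with the name of the per-row winner.
#'
#' @param scenarios data frame with columns `n`, `p`, `rho`.
#' @param n_rep replications per scenario.
#' @param seed master seed (each scenario uses `seed + row - 1`).
#' @param estimators estimator names.
#' @param ... further arguments passed to [run_scenario()].
#' @return data frame with scenario columns, one EMSE column per estimator,
#'   and a `best` column.
#' @export
emse_table <- function(scenarios, n_rep = 2000L, seed = 1L,
                       estimators = default_estimator_set(), ...) {
  stopifnot(all(c("n", "p", "rho") %in% names(scenarios)))
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    res <- run_scenario(scenarios$n[i], scenarios$p[i], scenarios$rho[i],
                        n_rep = n_rep, seed = seed + i - 1L,
                        estimators = estimators, ...)
    c(list(n = scenarios$n[i], p = scenarios$p[i], rho = scenarios$rho[i]),
      as.list(res$emse), list(best = names(which.min(res$emse))))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}
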