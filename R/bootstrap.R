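#' Bootstrap SMSE evaluation of shrinkage estimators on a count dataset
#'
#' Case bootstrap: rows of the dataset are resampled with replacement B
#' times; on each resample the Poisson GLM is refitted and every configured
#' estimator is evaluated. The reference ("true") coefficient vector is the
#' mean of the B maximum-likelihood estimates, and the scalar risk of an
#' estimator is
#' \deqn{SMSE = \frac{1}{B}\sum_b \|\hat\beta_b - \bar\beta_{MLE}\|^2,}
#' with the variance part `mean_b ||beta_b - mean_b(beta_b)||^2` reported
#' separately (so `SMSE = variance + squared bias` by construction, and
#' `SMSE >= variance` always).
#'
#' Biasing parameters are, by default, re-estimated on each resample so the
#' reported risk reflects the variability of the whole pipeline; set
#' `refit_rules = FALSE` to freeze them at their full-data values.
#' Resamples whose design is rank deficient are redrawn (up to `max_retry`
#' times) and then skipped and counted; a warning is issued when more than
#' 5% of resamples are skipped.
#'
#' @param data a `count_dataset` with a response.
#' @param B number of bootstrap resamples (default 10000).
#' @param seed master seed; resample b uses `seed + b`.
#' @param estimators estimator names (see [default_estimator_set()]).
#' @param refit_rules re-estimate biasing parameters per resample
#'   (default `TRUE`).
#' @param standardize standardize each resampled design before fitting
#'   (default `TRUE`, matching the usual pre-processing for these
#'   estimators).
#' @param max_retry redraw attempts for rank-deficient resamples.
#' @param resample_indices optional hook `function(b, n)` returning the row
#'   indices of resample b (for deterministic tests); default is uniform
#'   sampling with replacement.
#' @return an object of class `bootstrap_result`: `table` (data frame with
#'   estimator, k, d, variance, smse), `coef_means` (estimator x
#'   coefficient matrix), `beta_ref`, `B`, `skipped`.
#' @export
bootstrap_smse <- function(data, B = 10000L, seed = 1L,
                           estimators = default_estimator_set(),
                           refit_rules = TRUE, standardize = TRUE,
                           max_retry = 10L, resample_indices = NULL) {
  stopifnot(inherits(data, "count_dataset"), B >= 1)
  validate_count_dataset(data, need_response = TRUE)
  n <- n_obs(data)

  prepare <- function(d) if (standardize && !d$standardized) standardize_dataset(d) else d
  full_fit <- fit_poisson_mle(prepare(data))
  if (!full_fit$converged) stop("full-data fit did not converge", call. = FALSE)
  frozen_specs <- NULL
  if (!refit_rules) {
    full_inputs <- biasing_inputs(full_fit)
    frozen_specs <- lapply(stats::setNames(estimators, estimators),
                           resolve_estimator, inputs = full_inputs)
  }

  ncoef <- length(full_fit$beta_mle)
  coefs <- lapply(stats::setNames(estimators, estimators),
                  function(nm) matrix(NA_real_, B, ncoef))
  mle_coefs <- matrix(NA_real_, B, ncoef)
  skipped <- 0L

  for (b in seq_len(B)) {
    set.seed(seed + b)
    fit <- NULL
    for (attempt in seq_len(max_retry + 1L)) {
      idx <- if (is.null(resample_indices)) {
        sample.int(n, n, replace = TRUE)
      } else {
        resample_indices(b, n)
      }
      d_b <- data
      d_b$design <- data$design[idx, , drop = FALSE]
      d_b$response <- data$response[idx]
      d_b$standardized <- FALSE
      d_b$scaling_record <- NULL
      if (qr(d_b$design)$rank < ncol(d_b$design)) next
      d_b <- tryCatch(prepare(d_b), error = function(e) NULL)
      if (is.null(d_b)) next
      fit <- tryCatch(fit_poisson_mle(d_b), error = function(e) NULL)
      if (!is.null(fit) && fit$converged) break
      fit <- NULL
      if (!is.null(resample_indices)) break  # deterministic hook: no retry
    }
    if (is.null(fit)) {
      skipped <- skipped + 1L
      next
    }
    canon <- canonical_decompose(fit)
    inputs <- if (refit_rules) biasing_inputs(fit, canon) else NULL
    mle_coefs[b, ] <- fit$beta_mle
    for (nm in estimators) {
      spec <- if (refit_rules) {
        suppressWarnings(resolve_estimator(nm, inputs))
      } else {
        frozen_specs[[nm]]
      }
      h <- shrink_factors(spec, canon$lambda)
      coefs[[nm]][b, ] <- drop(canon$Q %*% (h * canon$alpha))
    }
  }

  ok <- !is.na(mle_coefs[, 1])
  if (!any(ok)) stop("every bootstrap resample failed", call. = FALSE)
  if (skipped > 0.05 * B) {
    warning(sprintf("%d of %d resamples skipped (rank deficiency or non-convergence)",
                    skipped, B), call. = FALSE)
  }
  beta_ref <- colMeans(mle_coefs[ok, , drop = FALSE])

  full_inputs <- biasing_inputs(full_fit)
  rows <- lapply(estimators, function(nm) {
    cc <- coefs[[nm]][ok, , drop = FALSE]
    m <- colMeans(cc)
    dev_ref <- sweep(cc, 2, beta_ref)
    dev_mean <- sweep(cc, 2, m)
    spec <- if (refit_rules) {
      suppressWarnings(resolve_estimator(nm, full_inputs))
    } else {
      frozen_specs[[nm]]
    }
    data.frame(estimator = nm,
               k = if (is.null(spec$k)) NA_real_ else spec$k,
               d = if (is.null(spec$d)) NA_real_ else spec$d,
               variance = mean(rowSums(dev_mean^2)),
               smse = mean(rowSums(dev_ref^2)))
  })
  table <- do.call(rbind, rows)
  coef_means <- t(vapply(estimators,
                         function(nm) colMeans(coefs[[nm]][ok, , drop = FALSE]),
                         numeric(ncoef)))
  colnames(coef_means) <- names(full_fit$beta_mle)
  structure(
    list(table = table, coef_means = coef_means, beta_ref = beta_ref,
         B = B, skipped = skipped, refit_rules = refit_rules),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: B = %d (%d skipped), rules %s\n",
              x$B, x$skipped,
              if (x$refit_rules) "re-estimated per resample" else "frozen"))
  tab <- x$table
  tab$variance <- round(tab$variance, 4)
  tab$smse <- round(tab$smse, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a bootstrap evaluation as CSV
#'
#' Emits one row per estimator: label, biasing parameters, coefficient
#' means, variance and SMSE.
#'
#' @param result a `bootstrap_result`.
#' @param path output path.
#' @export
write_bootstrap_csv <- function(result, path) {
  stopifnot(inherits(result, "bootstrap_result"))
  out <- cbind(result$table, as.data.frame(result$coef_means))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
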