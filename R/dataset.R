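#' Construct a count-regression dataset
#'
#' Bundles a design matrix and a non-negative integer response together with
#' the bookkeeping needed by the fitting and shrinkage machinery: whether an
#' intercept column is present, whether the covariate columns have been
#' centred and scaled to unit length, and the centring/scaling record needed
#' to map coefficients back to the raw scale.
#'
#' @param x numeric matrix (or data frame) of covariates, one row per
#'   observation. Must not contain an intercept column; use
#'   `add_intercept = TRUE` to prepend one.
#' @param y integer vector of non-negative counts, or `NULL` for a
#'   design-only object (as produced by [generate_design()] before responses
#'   are simulated).
#' @param add_intercept prepend a column of ones to the design.
#' @param column_names optional covariate names; defaults to the column
#'   names of `x` or `x1`, `x2`, ...
#' @return An object of class `count_dataset` with elements `design`
#'   (n x (p+1) matrix when an intercept is present), `response`,
#'   `include_intercept`, `standardized`, `column_names`, `scaling_record`.
#' @seealso [standardize_dataset()], [read_count_csv()], [fit_poisson_mle()]
#' @export
count_dataset <- function(x, y = NULL, add_intercept = TRUE,
                          column_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(column_names)) {
    column_names <- colnames(x)
    if (is.null(column_names)) column_names <- paste0("x", seq_len(ncol(x)))
  }
  if (ncol(x) > 0) colnames(x) <- column_names
  design <- if (add_intercept) {
    cbind("(Intercept)" = rep(1, nrow(x)), x)
  } else {
    x
  }
  obj <- structure(
    list(design = design,
         response = if (is.null(y)) NULL else as.numeric(y),
         include_intercept = add_intercept,
         standardized = FALSE,
         column_names = column_names,
         scaling_record = NULL),
    class = "count_dataset")
  validate_count_dataset(obj)
  obj
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: n = %d, p = %d covariate(s)%s%s%s\n",
              n_obs(x), n_covariates(x),
              if (x$include_intercept) ", intercept" else "",
              if (x$standardized) ", standardized" else "",
              if (is.null(x$response)) ", design only" else ""))
  invisible(x)
}

#' Number of observations / covariates of a dataset
#' @param data a `count_dataset`.
#' @return integer count.
#' @export
n_obs <- function(data) nrow(data$design)

#' @rdname n_obs
#' @export
n_covariates <- function(data) ncol(data$design) - as.integer(data$include_intercept)

validate_count_dataset <- function(data, need_response = FALSE) {
  y <- data$response
  if (need_response && is.null(y)) {
    stop("dataset has no response; supply counts before fitting", call. = FALSE)
  }
  if (!is.null(y)) {
    if (length(y) != nrow(data$design)) {
      stop("response length does not match the number of design rows", call. = FALSE)
    }
    bad <- which(!is.finite(y) | y < 0 | abs(y - round(y)) > 1e-8)
    if (length(bad) > 0) {
      stop(sprintf("response must contain non-negative integers; first offending row: %d (value %s)",
                   bad[1], format(y[bad[1]])), call. = FALSE)
    }
    # n > p + 1 keeps the sigma2 denominator n - p - 1 positive
    if (nrow(data$design) <= n_covariates(data) + 1) {
      stop(sprintf("need n > p + 1 (got n = %d with p = %d covariates)",
                   nrow(data$design), n_covariates(data)), call. = FALSE)
    }
  }
  if (isTRUE(data$standardized)) {
    cols <- covariate_columns(data)
    ss <- colSums(data$design[, cols, drop = FALSE]^2)
    if (any(abs(ss - 1) > 1e-10)) {
      stop("standardized dataset must have unit-length covariate columns", call. = FALSE)
    }
  }
  invisible(data)
}

covariate_columns <- function(data) {
  if (data$include_intercept) seq(2L, ncol(data$design)) else seq_len(ncol(data$design))
}

#' Centre covariates and scale them to unit column length
#'
#' Each covariate column is centred and divided by its root sum of squares so
#' that the column has unit length; the intercept column (if any) is left
#' untouched. The centres and scales are stored in `scaling_record` so that
#' coefficients estimated on the standardized scale can be mapped back with
#' [destandardize_coef()]. This is the conventional pre-processing for
#' ridge-type estimation, under which the biasing parameter k is comparable
#' across datasets.
#'
#' @param data a `count_dataset`.
#' @return a standardized `count_dataset`.
#' @export
standardize_dataset <- function(data) {
  stopifnot(inherits(data, "count_dataset"))
  if (isTRUE(data$standardized)) return(data)
  cols <- covariate_columns(data)
  xs <- data$design[, cols, drop = FALSE]
  center <- colMeans(xs)
  xc <- sweep(xs, 2, center)
  scale <- sqrt(colSums(xc^2))
  zero <- which(scale < 1e-12)
  if (length(zero) > 0) {
    stop(sprintf("cannot standardize zero-variance column '%s'",
                 data$column_names[zero[1]]), call. = FALSE)
  }
  data$design[, cols] <- sweep(xc, 2, scale, "/")
  data$standardized <- TRUE
  data$scaling_record <- list(center = center, scale = scale)
  validate_count_dataset(data)
  data
}

#' Map standardized-scale coefficients back to the raw covariate scale
#'
#' @param data the standardized `count_dataset` the coefficients were
#'   estimated on (its `scaling_record` is used).
#' @param beta coefficient vector on the standardized scale (intercept first
#'   when the dataset has one).
#' @return coefficient vector on the raw scale.
#' @export
destandardize_coef <- function(data, beta) {
  stopifnot(inherits(data, "count_dataset"), isTRUE(data$standardized))
  rec <- data$scaling_record
  if (!data$include_intercept) {
    return(beta / rec$scale)
  }
  slopes <- beta[-1] / rec$scale
  intercept <- beta[1] - sum(slopes * rec$center)
  out <- c(intercept, slopes)
  names(out) <- colnames(data$design)
  out
}

#' Read a count-regression dataset from a delimited text file
#'
#' Expects a header row; every column other than `response` is treated as a
#' covariate. The response must consist of non-negative integers with no
#' missing values (no imputation is performed).
#'
#' @param path file path (CSV, or TSV with `sep = "\t"`).
#' @param response name of the response column.
#' @param add_intercept prepend an intercept column (default `TRUE`).
#' @param sep field separator passed to [utils::read.table()].
#' @return a `count_dataset`.
#' @export
read_count_csv <- function(path, response, add_intercept = TRUE, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (nrow(df) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (!response %in% names(df)) {
    stop(sprintf("response column '%s' not found (columns: %s)",
                 response, paste(names(df), collapse = ", ")), call. = FALSE)
  }
  y <- df[[response]]
  if (anyNA(df)) {
    stop("missing values are not supported; clean the input first", call. = FALSE)
  }
  bad <- which(!is.numeric(y) | y < 0 | abs(y - round(y)) > 1e-8)
  if (length(bad) > 0) {
    stop(sprintf("response column '%s' must be non-negative integers; first offending row: %d",
                 response, bad[1]), call. = FALSE)
  }
  x <- as.matrix(df[setdiff(names(df), response)])
  if (!is.numeric(x)) stop("covariate columns must be numeric", call. = FALSE)
  count_dataset(x, y, add_intercept = add_intercept)
}

#' Write a count-regression dataset to CSV
#'
#' Inverse of [read_count_csv()]: writes the covariate columns (raw design,
#' without the intercept column) plus the response.
#'
#' @param data a `count_dataset` with a response.
#' @param path output file path.
#' @param response name for the response column.
#' @export
write_count_csv <- function(data, path, response = "y") {
  stopifnot(inherits(data, "count_dataset"), !is.null(data$response))
  x <- data$design[, covariate_columns(data), drop = FALSE]
  df <- as.data.frame(x)
  df[[response]] <- data$response
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
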