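#' Generate a synthetic count-regression fixture dataset
#'
#' Produces small, fully synthetic datasets for demonstrations and tests,
#' optionally written to CSV (deterministic for a given seed, byte for
#' byte).
#'
#' \describe{
#'   \item{aircraft_like}{A synthetic stand-in shaped like the classic
#'     aircraft-damage data: n = 30, one binary covariate (aircraft type),
#'     a bomb-load covariate on a tons scale correlated with the type, and
#'     an aircrew-experience covariate on a months scale. Counts are drawn
#'     from a Poisson model with a linear predictor on the raw scale. The
#'     very different column scales give the raw `X'X` a large condition
#'     number, mimicking the multicollinearity of the real data. This is
#'     NOT the real dataset — coefficients and risks computed from it are
#'     illustrative only.}
#'   \item{collinear_toy}{n = 50 draws of a p = 3 collinear design (see
#'     [generate_design()]) at the given `rho`, with Poisson counts from
#'     the principal-eigenvector coefficient vector of [true_beta()].}
#' }
#'
#' @param kind `"aircraft_like"` or `"collinear_toy"`.
#' @param seed seed for reproducibility.
#' @param path optional CSV output path (written with [write_count_csv()]).
#' @param rho collinearity level for `"collinear_toy"` (default 0.99).
#' @return a `count_dataset` (with attribute `"path"` when written).
#' @export
generate_fixture <- function(kind = c("aircraft_like", "collinear_toy"),
                             seed = 1L, path = NULL, rho = 0.99) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "aircraft_like") {
    n <- 30L
    x1 <- stats::rbinom(n, 1, 0.5)
    x2 <- round(4 + 6 * x1 + stats::runif(n, 0, 4), 2)
    x3 <- round(80 + 15 * stats::rnorm(n) + 10 * x1)
    eta <- -0.4 + 0.55 * x1 + 0.18 * x2 - 0.013 * x3
    y <- stats::rpois(n, exp(eta))
    data <- count_dataset(cbind(x1 = x1, x2 = x2, x3 = x3), y)
  } else {
    design <- generate_design(50L, 3L, rho, seed = seed, standardize = FALSE,
                              intercept = TRUE)
    beta <- true_beta(design)
    y <- stats::rpois(50L, exp(drop(design$design %*% beta)))
    design$response <- as.numeric(y)
    validate_count_dataset(design)
    data <- design
  }
  if (!is.null(path)) {
    write_count_csv(data, path)
    attr(data, "path") <- path
  }
  data
}
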