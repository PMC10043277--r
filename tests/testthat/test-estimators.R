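test_that("biasing rules evaluate linearly and differentiate exactly", {
  r <- g_rule(slope = 0.4, intercept = -0.2)
  expect_equal(rule_value(r, c(0, 1, 2.5)), c(-0.2, 0.2, 0.8))
  expect_equal(rule_deriv(r, c(0, 3)), c(0.4, 0.4))
  q <- g_rule(form = "quadratic", fun = function(k) k^2 - k)
  expect_equal(rule_value(q, 2), 2)
  expect_equal(rule_deriv(q, 2), 3, tolerance = 1e-6)
  expect_error(g_rule(form = "custom"), "fun")
  expect_error(g_rule(slope = 1, intercept = 0, provenance = "g1", c = 1.2),
               "c in \\(0, 1\\)")
})

test_that("spec validation enforces the admissible parameter ranges", {
  expect_error(shrinkage_spec("PRE"), "k >= 0")
  expect_error(shrinkage_spec("PRE", k = -1), "k >= 0")
  expect_error(shrinkage_spec("PLE", d = 1.2), "d in")
  expect_error(shrinkage_spec("PRTE", k = 1), "rule")
  expect_warning(shrinkage_spec("PHY", k = 1, d = 1.5), "admissible")
})

test_that("parameter choices that cancel the matrix factors reduce to the MLE", {
  fit <- fit_poisson_mle(toy_dataset(seed = 21, n = 40, p = 3))
  b <- fit$beta_mle
  expect_equal(apply_shrinkage(shrinkage_spec("PRE", k = 0), fit), b,
               tolerance = 1e-12)
  expect_equal(apply_shrinkage(shrinkage_spec("PLE", d = 1), fit), b,
               tolerance = 1e-12)
  expect_equal(apply_shrinkage(shrinkage_spec("PLTE", k = 0.7, d = -0.7), fit),
               b, tolerance = 1e-12)
  expect_equal(apply_shrinkage(shrinkage_spec("PTPE", k = 0.7, d = 1), fit), b,
               tolerance = 1e-12)
})

test_that("two-parameter toy systems match hand algebra", {
  fit <- fake_fit(diag(c(4, 1)), c(1, 1))
  expect_equal(apply_shrinkage(shrinkage_spec("PRE", k = 1), fit),
               c(4 / 5, 1 / 2), tolerance = 1e-12, ignore_attr = TRUE)
  # improved Liu-type on the ridge base, f(k) = 0.05 k + 0.05 at k = 1
  spec <- shrinkage_spec("ILTE_PRE", k = 1,
                         rule = g_rule(slope = 0.05, intercept = 0.05))
  expect_equal(apply_shrinkage(spec, fit),
               c(4.1 / 5 * 4 / 5, 1.1 / 2 * 1 / 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("improved Liu-type with f(k) = k leaves the base estimator unchanged", {
  fit <- fit_poisson_mle(toy_dataset(seed = 4, n = 35, p = 2))
  ident <- g_rule(slope = 1, intercept = 0)
  spec <- shrinkage_spec("ILTE", k = 0.8, rule = ident)
  expect_equal(ilte(spec, fit), fit$beta_mle, tolerance = 1e-12)
  spec0 <- shrinkage_spec("ILTE", k = 0, rule = g_rule(slope = 0, intercept = 0))
  expect_equal(ilte(spec0, fit), fit$beta_mle, tolerance = 1e-12)
  # nested base: plugging the ridge base reproduces the ILTE_PRE family
  pre_base <- shrinkage_spec("PRE", k = 0.8)
  spec_nested <- shrinkage_spec("ILTE", k = 0.8, rule = ident, base = pre_base)
  expect_equal(apply_shrinkage(spec_nested, fit),
               apply_shrinkage(shrinkage_spec("PRE", k = 0.8), fit),
               tolerance = 1e-12)
})

test_that("ridge-type special cases collapse onto the named families", {
  fit <- fake_fit(random_pd(3, seed = 5), c(0.8, -0.4, 0.2))
  k <- 0.6
  d0 <- 0.35
  # g == 1 -> ridge estimator
  expect_equal(prte(shrinkage_spec("PRTE", k = k,
                                   rule = g_rule(slope = 0, intercept = 1)), fit),
               apply_shrinkage(shrinkage_spec("PRE", k = k), fit),
               tolerance = 1e-12)
  # k = 0 with g(0) = 1 -> MLE
  expect_equal(prte(shrinkage_spec("PRTE", k = 0,
                                   rule = g_rule(slope = 2, intercept = 1)), fit),
               fit$beta_mle, tolerance = 1e-12)
  # constant g = d -> PHY family
  expect_equal(prte(shrinkage_spec("PRTE", k = k,
                                   rule = g_rule(slope = 0, intercept = d0)), fit),
               apply_shrinkage(shrinkage_spec("PHY", k = k, d = d0), fit),
               tolerance = 1e-12)
  # unit slope, intercept d -> PSK family
  expect_equal(prte(shrinkage_spec("PRTE", k = k,
                                   rule = g_rule(slope = 1, intercept = d0)), fit),
               apply_shrinkage(shrinkage_spec("PSK", k = k, d = d0), fit),
               tolerance = 1e-12)
  # k = 0 with g(0) = d -> Liu estimator
  expect_equal(prte(shrinkage_spec("PRTE", k = 0,
                                   rule = g_rule(slope = 1, intercept = d0)), fit),
               apply_shrinkage(shrinkage_spec("PLE", d = d0), fit),
               tolerance = 1e-12)
})

test_that("direct solves agree with the induced linear map for every family", {
  fit <- fake_fit(random_pd(4, seed = 17), c(1, -0.5, 0.25, 0.1))
  rule <- g_rule(slope = 0.3, intercept = -0.1)
  specs <- list(
    shrinkage_spec("MLE"),
    shrinkage_spec("PRE", k = 0.7),
    shrinkage_spec("PLE", d = 0.4),
    shrinkage_spec("PLTE", k = 0.7, d = -0.9),
    shrinkage_spec("PTPE", k = 0.7, d = 0.4),
    shrinkage_spec("PHY", k = 0.7, d = 0.4),
    shrinkage_spec("PSK", k = 0.7, d = 1.3),
    shrinkage_spec("ILTE", k = 0.7, rule = rule),
    shrinkage_spec("ILTE_PRE", k = 0.7, rule = rule),
    shrinkage_spec("PRTE", k = 0.7, rule = rule))
  for (spec in specs) {
    H <- induced_map(spec, fit)
    expect_equal(apply_shrinkage(spec, fit), drop(H %*% fit$beta_mle),
                 tolerance = 1e-12, ignore_attr = TRUE,
                 label = spec$family)
  }
})

test_that("ridge shrinkage is strictly monotone in k, componentwise", {
  canon <- random_canon(4, seed = 8)
  ks <- c(0.1, 0.5, 1, 3, 10)
  mags <- sapply(ks, function(k)
    abs(shrink_factors(shrinkage_spec("PRE", k = k), canon$lambda) * canon$alpha))
  for (j in seq_along(canon$alpha)) {
    expect_true(all(diff(mags[j, ]) < 0))
  }
})

test_that("ridge-type norm is bounded by the operator-norm product", {
  fit <- fake_fit(random_pd(3, seed = 23), c(1, 0.5, -0.3))
  rule <- g_rule(slope = 0, intercept = 0.8)  # bounded g
  for (k in c(0.5, 5, 50, 500)) {
    b_pre <- apply_shrinkage(shrinkage_spec("PRE", k = k), fit)
    b_prte <- prte(shrinkage_spec("PRTE", k = k, rule = rule), fit)
    lam <- eigen(fit$xtwx, symmetric = TRUE, only.values = TRUE)$values
    opnorm <- max(abs((lam + 0.8) / (lam + 1)))
    expect_lte(sqrt(sum(b_prte^2)), opnorm * sqrt(sum(b_pre^2)) + 1e-12)
  }
})
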