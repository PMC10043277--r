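test_that("MLE risk is the rotated inverse information", {
  canon <- random_canon(4, seed = 2)
  rep <- mmse_matrix(shrinkage_spec("MLE"), canon)
  expect_equal(rep$mmse,
               canon$Q %*% diag(1 / canon$lambda) %*% t(canon$Q),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rep$smse, sum(1 / canon$lambda), tolerance = 1e-12)
  expect_equal(rep$bias_vector, rep(0, 4), tolerance = 1e-14)
  expect_equal(rep$bias_sq_part, 0)
})

test_that("scalar risk equals the trace of the matrix risk for every family", {
  set.seed(19)
  rule <- g_rule(slope = 0.3, intercept = -0.2)
  for (r in 1:5) {
    canon <- random_canon(sample(2:5, 1))
    alpha <- rnorm(length(canon$lambda))
    specs <- list(shrinkage_spec("MLE"),
                  shrinkage_spec("PRE", k = runif(1, 0.1, 2)),
                  shrinkage_spec("PLE", d = runif(1)),
                  shrinkage_spec("PLTE", k = runif(1, 0.1, 2), d = rnorm(1)),
                  shrinkage_spec("PTPE", k = runif(1, 0.1, 2), d = runif(1)),
                  shrinkage_spec("PHY", k = runif(1, 0.1, 2), d = runif(1)),
                  shrinkage_spec("PSK", k = runif(1, 0.1, 2), d = rnorm(1)),
                  shrinkage_spec("ILTE", k = runif(1, 0.1, 2), rule = rule),
                  shrinkage_spec("ILTE_PRE", k = runif(1, 0.1, 2), rule = rule),
                  shrinkage_spec("PRTE", k = runif(1, 0.1, 2), rule = rule))
    for (spec in specs) {
      rep <- mmse_matrix(spec, canon, alpha)
      expect_equal(smse(spec, canon, alpha), sum(diag(rep$mmse)),
                   tolerance = 1e-10, label = spec$family)
      expect_equal(rep$smse, rep$variance_part + rep$bias_sq_part,
                   tolerance = 1e-10)
      expect_equal(rep$mmse, t(rep$mmse), tolerance = 1e-12)
    }
  }
})

test_that("single-component ridge-type risk matches hand arithmetic", {
  # lambda = 2, alpha = 1, k = 1, g == 0:
  # variance 2*(2+0)^2/(3^2 3^2) = 8/81, bias^2 ((0-1-1)*2-1)^2/81 = 25/81
  canon <- canonical_form(lambda = 2, alpha = 1, n = 10, p = 0, sigma2 = 1)
  spec <- shrinkage_spec("PRTE", k = 1, rule = g_rule(slope = 0, intercept = 0))
  expect_equal(smse(spec, canon, alpha = 1), 33 / 81, tolerance = 1e-12)
  rep <- mmse_matrix(spec, canon, alpha = 1)
  expect_equal(rep$variance_part, 8 / 81, tolerance = 1e-12)
  expect_equal(rep$bias_sq_part, 25 / 81, tolerance = 1e-12)
})

test_that("risk-level reduction identities of the ridge-type family hold", {
  canon <- random_canon(3, seed = 11)
  alpha <- c(0.7, -0.2, 1.1)
  k <- 0.8
  d0 <- 0.45
  pairs <- list(
    list(shrinkage_spec("PRTE", k = k, rule = g_rule(slope = 0, intercept = 1)),
         shrinkage_spec("PRE", k = k)),
    list(shrinkage_spec("PRTE", k = 0, rule = g_rule(slope = 3, intercept = 1)),
         shrinkage_spec("MLE")),
    list(shrinkage_spec("PRTE", k = 0, rule = g_rule(slope = 1, intercept = d0)),
         shrinkage_spec("PLE", d = d0)),
    list(shrinkage_spec("PRTE", k = k, rule = g_rule(slope = 0, intercept = d0)),
         shrinkage_spec("PHY", k = k, d = d0)),
    list(shrinkage_spec("PRTE", k = k, rule = g_rule(slope = 1, intercept = d0)),
         shrinkage_spec("PSK", k = k, d = d0)))
  for (pr in pairs) {
    expect_equal(mmse_matrix(pr[[1]], canon, alpha)$mmse,
                 mmse_matrix(pr[[2]], canon, alpha)$mmse,
                 tolerance = 1e-12,
                 label = pr[[2]]$family)
  }
})

test_that("closed-form risk matches a sampling oracle for the MLE law", {
  # draws from the asymptotic distribution of the MLE, pushed through H
  set.seed(101)
  canon <- canonical_form(lambda = c(4, 1), alpha = c(0, 0), n = 20, p = 1,
                          sigma2 = 1)
  alpha <- c(1, 1)
  spec <- shrinkage_spec("PRTE", k = 1,
                         rule = g_rule(slope = 0.5, intercept = -0.05))
  rep <- mmse_matrix(spec, canon, alpha, rotate = FALSE)
  h <- shrink_factors(spec, canon$lambda)
  ndraw <- 2e5
  draws <- cbind(rnorm(ndraw, alpha[1], sqrt(1 / 4)),
                 rnorm(ndraw, alpha[2], 1))
  err <- sweep(draws, 2, h, "*")
  err <- sweep(err, 2, alpha)
  for (i in 1:2) for (j in 1:2) {
    prods <- err[, i] * err[, j]
    se <- sd(prods) / sqrt(ndraw)
    expect_lt(abs(mean(prods) - rep$mmse[i, j]), 3 * se + 1e-12)
  }
})

test_that("the SMSE derivative matches central finite differences", {
  set.seed(57)
  for (r in 1:5) {
    canon <- random_canon(sample(2:5, 1))
    alpha <- rnorm(length(canon$lambda))
    rule <- g_rule(slope = runif(1, 0, 1), intercept = rnorm(1, 0, 0.3))
    for (k in c(0.2, 0.9, 1.7)) {
      eps <- 1e-6
      spec_hi <- shrinkage_spec("PRTE", k = k + eps, rule = rule)
      spec_lo <- shrinkage_spec("PRTE", k = k - eps, rule = rule)
      fd <- (smse(spec_hi, canon, alpha) - smse(spec_lo, canon, alpha)) / (2 * eps)
      an <- smse_derivative(rule, canon, alpha, k)
      expect_lt(abs(an - fd), 1e-5 * (1 + abs(an)))
    }
  }
})

test_that("both stationarity lines flatten the single-component risk", {
  canon <- canonical_form(lambda = 1.7, alpha = 0.8, n = 30, p = 0, sigma2 = 1)
  inp <- biasing_inputs(canon)
  ks <- seq(0.1, 3, by = 0.3)
  # integration-constant family: g = ck + (c-1) lambda
  for (cc in c(0.2, 0.5, 0.8)) {
    g <- g_rule(slope = cc, intercept = (cc - 1) * 1.7)
    expect_equal(smse_derivative(g, canon, k = ks), rep(0, length(ks)),
                 tolerance = 1e-10)
  }
  # stationarity line of the bias factor
  g2 <- make_g_rule("fact2_line", inp, j = 1)
  expect_equal(smse_derivative(g2, canon, k = ks), rep(0, length(ks)),
               tolerance = 1e-10)
  # and by finite differences on the risk itself
  for (k in c(0.5, 1.5)) {
    eps <- 1e-4
    fd <- (smse(shrinkage_spec("PRTE", k = k + eps, rule = g2), canon) -
             smse(shrinkage_spec("PRTE", k = k - eps, rule = g2), canon)) / (2 * eps)
    expect_lt(abs(fd), 1e-8)
  }
})

test_that("superiority verdicts behave on the archetypal cases", {
  canon <- random_canon(3, seed = 41)
  f <- g_rule(slope = 0.05, intercept = 0.05)
  # g far outside the admissible interval
  rep_big <- prte_superiority(f, g_rule(slope = 0, intercept = 1e6),
                              canon, k = 1)
  expect_false(rep_big$interval_ok)
  expect_false(rep_big$mmse_difference_pd)
  # zero true coefficients: no bias, the variance gap decides
  g <- g_rule(slope = 0.5, intercept = -0.05)
  rep0 <- prte_superiority(f, g, canon, alpha = rep(0, 3), k = 1)
  expect_true(rep0$interval_ok)
  expect_equal(rep0$condition22_value, 0)
  expect_true(rep0$condition22_ok)
  expect_true(rep0$mmse_difference_pd)
})

test_that("interval plus quadratic-form verdict equals the direct eigencheck", {
  set.seed(71)
  n_pd <- 0
  for (r in 1:400) {
    m <- sample(2:4, 1)
    canon <- random_canon(m)
    alpha <- rnorm(m, sd = sample(c(0.2, 1), 1))
    f <- g_rule(slope = runif(1, 0, 1), intercept = runif(1, -0.2, 0.5))
    g <- g_rule(slope = runif(1, 0, 1), intercept = runif(1, -1, 1))
    k <- runif(1, 0.05, 2)
    rep <- prte_superiority(f, g, canon, alpha, k)
    # independent assembly of the theorem's matrix difference (naive loops)
    lam <- canon$lambda
    fv <- rule_value(f, k)
    gv <- rule_value(g, k)
    D <- matrix(0, m, m)
    b <- numeric(m)
    for (j in seq_len(m)) {
      D[j, j] <- (lam[j] + fv)^2 / (lam[j] * (lam[j] + k)^2) -
        lam[j] * (lam[j] + gv)^2 / ((lam[j] + 1)^2 * (lam[j] + k)^2)
      b[j] <- ((gv - k - 1) * lam[j] - k) * alpha[j] /
        ((lam[j] + 1) * (lam[j] + k))
    }
    direct <- is_pd(D - outer(b, b))
    expect_identical(rep$mmse_difference_pd, direct)
    if (rep$interval_ok && !is.na(rep$condition22_ok)) {
      expect_identical(rep$condition22_ok, rep$mmse_difference_pd)
    }
    if (direct) {
      n_pd <- n_pd + 1
      # the theorem's difference understates the full MMSE gap (it drops the
      # positive semidefinite ILTE bias term), so matrix dominance carries
      # over to the full risks, and to the scalar risks
      d_ilte <- mmse_matrix(shrinkage_spec("ILTE", k = k, rule = f), canon, alpha)
      d_prte <- mmse_matrix(shrinkage_spec("PRTE", k = k, rule = g), canon, alpha)
      expect_true(is_pd(d_ilte$mmse - d_prte$mmse))
      expect_gt(d_ilte$smse - d_prte$smse, 0)
    }
  }
  expect_gt(n_pd, 20)  # the sweep must actually exercise both verdicts
})

test_that("constant-g variance term is non-increasing in k", {
  canon <- random_canon(4, seed = 13)
  g <- g_rule(slope = 0, intercept = 0.6)
  ks <- seq(0.05, 3, by = 0.05)
  v <- sapply(ks, function(k)
    mmse_matrix(shrinkage_spec("PRTE", k = k, rule = g), canon)$variance_part)
  expect_true(all(diff(v) <= 1e-12))
})

test_that("risk sweep tabulates the estimator triplet over the grid", {
  canon <- random_canon(3, seed = 5)
  tab <- smse_sweep(canon, k_grid = seq(0, 1, by = 0.5))
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$estimator), c("ILTE", "ILTE_PRE", "PRTE"))
  expect_true(all(tab$smse >= tab$variance - 1e-12))
})
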