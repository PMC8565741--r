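test_that("null model fit recovers standard least-squares algebra", {
  set.seed(21)
  n <- 50
  x <- cbind(1, rbinom(n, 1, 0.5), runif(n))
  y <- drop(x %*% c(1, -2, 0.5)) + rnorm(n)
  nf <- fit_null(y, x)
  expect_s3_class(nf, "netkat_null")
  expect_lt(max(abs(crossprod(x, nf$residuals))), 1e-8 * max(abs(y)))
  expect_equal(nf$sigma2, sum(nf$residuals^2) / (n - 3))

  # intercept-only: residuals are centered y
  nf0 <- fit_null(y, matrix(1, n, 1))
  expect_equal(nf0$residuals, y - mean(y))

  expect_error(fit_null(y, cbind(x, x[, 2])), "rank")
  expect_error(fit_null(y[1:2], x[1:2, ]), "n > q")
})

test_that("coefficient recovery is unbiased over replicates", {
  set.seed(22)
  beta <- c(0.26, 0.5, 0.25)
  est <- replicate(200, {
    x <- cbind(1, rbinom(40, 1, 0.5), runif(40))
    y <- drop(x %*% beta) + rnorm(40)
    qr.coef(qr(x), y)
  })
  # mean estimate within 4 standard errors of the truth
  se <- apply(est, 1, sd) / sqrt(200)
  expect_true(all(abs(rowMeans(est) - beta) < 4 * se))
})

test_that("score statistic identities hold", {
  set.seed(23)
  n <- 30
  x <- cbind(1, rnorm(n))
  y <- rnorm(n)
  nf <- fit_null(y, x)
  # K = I: Q = r'r / sigma2 = n - q exactly
  expect_equal(score_statistic(nf, diag(n)), n - 2)
  expect_equal(score_statistic(nf, matrix(0, n, n)), 0)
  expect_equal(score_statistic(nf, 2.5 * diag(n)), 2.5 * (n - 2))

  nf_exact <- fit_null(drop(x %*% c(1, 2)), x)
  expect_error(score_statistic(nf_exact, diag(n)), "degenerate")
})

test_that("weighted chi-square tail matches exact and Monte Carlo values", {
  expect_equal(weighted_chisq_tail(1, qchisq(0.95, 1))$p, 0.05,
               tolerance = 1e-8)
  expect_equal(weighted_chisq_tail(c(1, 1), qchisq(0.95, 2))$p, 0.05,
               tolerance = 1e-8)
  # negative scale flips the tail: P(-2X > -2q) = P(X < q)
  expect_equal(weighted_chisq_tail(c(-2, -2), -2 * qchisq(0.3, 2))$p, 0.3,
               tolerance = 1e-8)

  set.seed(31)
  for (case in list(list(w = c(2, 1, 0.5, -0.5), t = 0),
                    list(w = c(2, 1, 0.5, -0.5), t = 3),
                    list(w = c(1.5, -1, 0.3, 0.3, -0.2), t = 1))) {
    got <- weighted_chisq_tail(case$w, case$t)
    mc <- oracle_weighted_chisq_tail(case$w, case$t)
    expect_true(got$davies_converged)
    expect_lt(abs(got$p - mc$p), 3 * mc$se)
  }
  expect_error(weighted_chisq_tail(c(0, 0), 1), "nonzero")
})

test_that("moment-matching fallback is accurate where it is exact", {
  # equal positive weights: the Liu approximation reduces to the exact
  # scaled chi-square, so the fallback path can be validated directly
  expect_equal(netkat:::liu_tail(rep(2, 5), 2 * qchisq(0.9, 5)), 0.1,
               tolerance = 1e-6)
  set.seed(32)
  w <- c(3, 2, 1, 0.5)
  mc <- oracle_weighted_chisq_tail(w, 8)
  expect_lt(abs(netkat:::liu_tail(w, 8) - mc$p), 0.01)
})

test_that("small-sample p-value agrees with the parametric bootstrap", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    n <- 20
    x <- cbind(1, rnorm(n))
    y <- rnorm(n)
    z <- matrix(rnorm(n * 5), n, 5)
    k <- gaussian_kernel(z, median_bandwidth(z))
    nf <- fit_null(y, x)
    got <- kernel_test_pvalue(nf, k)
    s_obs <- drop(crossprod(nf$residuals, k %*% nf$residuals)) /
      sum(nf$residuals^2)
    boot <- oracle_bootstrap_pvalue(nf, k, s_obs, draws = 2e5)
    expect_lt(abs(got$p_value - boot$p), 3 * max(boot$se, 1e-4))
  }
})

test_that("an identity-like kernel is reported as uninformative", {
  set.seed(41)
  n <- 15
  nf <- fit_null(rnorm(n), matrix(1, n, 1))
  expect_warning(res <- kernel_test_pvalue(nf, 3 * diag(n)), "uninformative")
  expect_equal(res$p_value, 1)
})

test_that("p-values are invariant to sample reordering", {
  set.seed(43)
  n <- 40
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  z <- matrix(rnorm(n * 6), n, 6)
  y <- rnorm(n) + 0.2 * rowSums(z)
  k <- gaussian_kernel(z, median_bandwidth(z))
  p1 <- kernel_test_pvalue(fit_null(y, x), k)$p_value
  perm <- sample(n)
  kp <- gaussian_kernel(z[perm, ], median_bandwidth(z[perm, ]))
  p2 <- kernel_test_pvalue(fit_null(y[perm], x[perm, ]), kp)$p_value
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("regularization vanishes continuously as tau approaches zero", {
  set.seed(44)
  g <- sample_ba_graph(8)
  z <- sample_features(precision_from_adjacency(g), 30)
  out <- sample_outcome(z, 0)
  nf <- fit_null(out$y, out$x)
  p_none <- kernel_test_pvalue(
    nf, gaussian_kernel(z, median_bandwidth(z)))$p_value
  lr <- regularize_laplacian(normalized_laplacian(g), 1e-6)
  zp <- project_features(z, lr)
  p_tiny <- kernel_test_pvalue(
    nf, gaussian_kernel(zp, median_bandwidth(zp)))$p_value
  expect_equal(p_tiny, p_none, tolerance = 1e-4)
})
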