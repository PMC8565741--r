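test_that("scale-free graphs are trees with the documented density", {
  g15 <- sample_ba_graph(15, seed = 61)
  expect_equal(n_edges(g15), 14L)
  expect_equal(n_edges(g15) / choose(15, 2), 14 / 105)
  g45 <- sample_ba_graph(45, seed = 62)
  expect_equal(n_edges(g45), 44L)
  for (p in c(5, 15, 30)) {
    expect_equal(count_components(sample_ba_graph(p)), 1L)
  }
})

test_that("densification adds the expected number of edges", {
  g <- sample_ba_graph(30, seed = 63)
  expect_equal(densify_graph(g, 0, seed = 1), g)
  full <- densify_graph(g, 1, seed = 1)
  expect_equal(n_edges(full), choose(30, 2))
  # mean density of 5%-densified 30-node graphs is about 0.12
  set.seed(64)
  dens <- replicate(400, {
    gd <- densify_graph(sample_ba_graph(30), 0.05)
    n_edges(gd) / choose(30, 2)
  })
  expect_lt(abs(mean(dens) -
                  (29 + 0.05 * (choose(30, 2) - 29)) / choose(30, 2)), 0.005)
  expect_lt(abs(mean(dens) - 0.12), 0.02)
})

test_that("precision construction is positive definite with edge zero pattern", {
  g2 <- pathway_graph(c("a", "b"), rbind(c("a", "b")))
  om <- precision_from_adjacency(g2)
  expect_equal(unname(om), rbind(c(1, 2 / 3), c(2 / 3, 1)))
  expect_equal(eigen(om, only.values = TRUE)$values, c(5 / 3, 1 / 3))

  expect_equal(unname(precision_from_adjacency(pathway_graph(letters[1:3]))),
               diag(3))

  set.seed(65)
  for (p in c(15, 30, 45)) {
    for (rep in 1:10) {
      g <- sample_ba_graph(p)
      om <- precision_from_adjacency(g)
      expect_gt(min(eigen(om, symmetric = TRUE, only.values = TRUE)$values), 0)
      a <- adjacency_matrix(g)
      offdiag <- om; diag(offdiag) <- 0
      expect_true(all((offdiag != 0) == (a == 1)))
    }
  }
})

test_that("feature draws follow the implied covariance", {
  g <- pathway_graph(letters[1:4],
                     rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  om <- precision_from_adjacency(g)
  z <- sample_features(om, 1e5, seed = 66)
  sig <- chol2inv(chol(om))
  err <- norm(cov(z) - sig, "F") / norm(sig, "F")
  expect_lt(err, 0.05)
  expect_true(all(abs(colMeans(z)) < 4 * sqrt(diag(sig)) / sqrt(1e5)))
  # determinism under a fixed seed
  expect_identical(sample_features(om, 10, seed = 9),
                   sample_features(om, 10, seed = 9))
  expect_error(sample_features(matrix(c(1, 2, 2, 1), 2), 5), "positive definite")
})

test_that("outcome model has the stated noise and effect structure", {
  g <- sample_ba_graph(5, seed = 67)
  z <- sample_features(precision_from_adjacency(g), 1e5)
  out <- sample_outcome(z, 0)
  resid <- out$y - 0.26 - 0.5 * out$x[, "x1"] - 0.25 * out$x[, "x2"]
  expect_equal(var(resid), 1.3688^2, tolerance = 0.02)
  # null construction: outcome uncorrelated with features
  expect_true(all(abs(cor(out$y, z)) < 4 / sqrt(1e5) * sd(out$y)))

  out1 <- sample_outcome(z, 0.1)
  fit <- qr.coef(qr(cbind(out1$x, z)), out1$y)
  expect_true(all(abs(fit[4:8] - 0.1) < 0.05))
})

test_that("low-degree node dropping follows the quantile rule", {
  # all degrees equal: nothing strictly below the 25th percentile
  ring <- pathway_graph(letters[1:5],
                        cbind(letters[1:5], letters[c(2:5, 1)]))
  expect_equal(drop_low_degree_nodes(ring, seed = 1)$kept, letters[1:5])

  # star K_{1,4}: leaves are eligible, each dropped about 25% of the time
  star <- pathway_graph(letters[1:5],
                        cbind(letters[1], letters[2:5]))
  set.seed(68)
  dropped <- replicate(4000, 5 - length(drop_low_degree_nodes(star)$kept))
  expect_equal(mean(dropped) / 4, 0.25, tolerance = 0.03)
  expect_identical(drop_low_degree_nodes(star, seed = 3),
                   drop_low_degree_nodes(star, seed = 3))
})

test_that("edge rewiring preserves counts and respects the original edges", {
  g <- sample_ba_graph(12, seed = 69)
  expect_equal(rewire_edges(g, 0), g, ignore_attr = TRUE)
  set.seed(70)
  for (frac in c(0.4, 1)) {
    for (rep in 1:10) {
      gr <- rewire_edges(g, frac)
      expect_equal(n_edges(gr), n_edges(g))
    }
  }
  # full rewiring of a 2-edge path in 4 nodes shares no original edge
  path <- pathway_graph(letters[1:4], rbind(c("a", "b"), c("b", "c")))
  set.seed(71)
  for (rep in 1:25) {
    gr <- rewire_edges(path, 1)
    expect_equal(n_edges(gr), 2L)
    shared <- intersect(netkat:::edge_key(gr$edges),
                        netkat:::edge_key(path$edges))
    expect_length(shared, 0)
  }
})

test_that("complete-mismatch graphs share no edges with the original", {
  set.seed(72)
  for (rep in 1:60) {
    g <- sample_ba_graph(15)
    g2 <- disjoint_edge_graph(g)
    expect_equal(n_edges(g2), 14L)
    expect_length(intersect(netkat:::edge_key(g$edges),
                            netkat:::edge_key(g2$edges)), 0)
  }
})

test_that("signal-to-noise ratio follows the quadratic form", {
  g <- sample_ba_graph(6, seed = 73)
  om <- precision_from_adjacency(g)
  expect_equal(signal_to_noise(rep(0, 6), om), 0)
  b <- runif(6)
  expect_equal(signal_to_noise(2 * b, om), 4 * signal_to_noise(b, om))
  # hand case: identity covariance, sigma^2-only denominator
  expect_equal(signal_to_noise(c(1, 1), diag(2), sigma2 = 0.5,
                               include_covariates = FALSE), 4)
})
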