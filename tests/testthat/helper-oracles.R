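# independent brute-force oracles used to freeze expected values

# median pairwise Euclidean distance by explicit double loop
oracle_median_bandwidth <- function(z) {
  n <- nrow(z)
  d <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, sqrt(sum((z[i, ] - z[j, ])^2)))
    }
  }
  median(d)
}

# Gaussian kernel by explicit double loop
oracle_gaussian_kernel <- function(z, rho) {
  n <- nrow(z)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      k[i, j] <- exp(-sum((z[i, ] - z[j, ])^2) / rho)
    }
  }
  k
}

# Monte Carlo tail probability of sum w_i * chisq_1
oracle_weighted_chisq_tail <- function(w, t, draws = 1e6) {
  x <- colSums(w * matrix(rchisq(length(w) * draws, df = 1), length(w)))
  est <- mean(x > t)
  list(p = est, se = sqrt(est * (1 - est) / draws))
}

# parametric bootstrap null distribution of the ratio statistic
# s = eps' P0 K P0 eps / eps' P0 eps, eps ~ N(0, I)
oracle_bootstrap_pvalue <- function(nf, k, s_obs, draws = 2e5) {
  pkp <- qr.resid(nf$qr, t(qr.resid(nf$qr, k)))
  pkp <- (pkp + t(pkp)) / 2
  m <- nf$n - nf$q
  lam <- eigen(pkp, symmetric = TRUE, only.values = TRUE)$values[1:m]
  xi <- matrix(rchisq(m * draws, df = 1), m)
  s_null <- colSums(lam * xi) / colSums(xi)
  est <- mean(s_null >= s_obs)
  list(p = est, se = sqrt(max(est * (1 - est), 1e-12) / draws))
}

# a random graph with a controllable mix of edges and isolated nodes
random_test_graph <- function(p, edge_prob = 0.2) {
  nodes <- paste0("v", seq_len(p))
  pairs <- t(combn(p, 2))
  pick <- runif(nrow(pairs)) < edge_prob
  edges <- if (any(pick)) {
    cbind(nodes[pairs[pick, 1]], nodes[pairs[pick, 2]])
  } else {
    NULL
  }
  pathway_graph(nodes, edges)
}
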