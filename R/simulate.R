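#' Sample a scale-free pathway graph
#'
#' Barabasi-Albert preferential attachment with one edge per new node
#' (m = 1), giving a connected tree with exactly p - 1 edges.  This matches
#' the low edge densities of curated metabolic pathways (density 2/p: 0.13,
#' 0.07, 0.04 at p = 15, 30, 45).
#'
#' @param p Number of nodes (>= 2).
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first.  All simulation functions in this package share this convention
#'   and otherwise draw from the current RNG stream.
#' @return A [pathway_graph()] with nodes `n1 ... np`.
#' @export
sample_ba_graph <- function(p, seed = NULL) {
  if (p < 2L) stop("`p` must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  ig <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)
  nodes <- paste0("n", seq_len(p))
  pathway_graph(nodes, cbind(nodes[el[, 1L]], nodes[el[, 2L]]))
}

#' Add random edges to a graph
#'
#' Every non-adjacent node pair independently becomes an edge with
#' probability `prob_add`.  Used to create the "medium" (5%) and "high"
#' (15%) density graphs that generate data in the missing-edge scenarios,
#' while the original sparse graph is the one handed to the test.
#'
#' @param g A [pathway_graph()].
#' @param prob_add Probability in \[0, 1\] of adding each absent edge.
#' @inheritParams sample_ba_graph
#' @return A [pathway_graph()] containing all original edges.
#' @export
densify_graph <- function(g, prob_add, seed = NULL) {
  stopifnot(inherits(g, "pathway_graph"), prob_add >= 0, prob_add <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- n_nodes(g)
  a <- adjacency_matrix(g)
  ut <- which(upper.tri(a) & a == 0, arr.ind = TRUE)
  if (nrow(ut)) {
    add <- ut[stats::runif(nrow(ut)) < prob_add, , drop = FALSE]
    edges <- rbind(g$edges, add)
  } else {
    edges <- g$edges
  }
  pathway_graph(g$nodes, cbind(g$nodes[edges[, 1L]], g$nodes[edges[, 2L]]))
}

#' Precision matrix from a graph's adjacency structure
#'
#' Standard diagonally dominant construction for Gaussian graphical model
#' simulation: set \eqn{\omega_{ij} = 1} for each edge, rescale each row's
#' off-diagonal entries by 1 / (1.5 x row absolute sum), symmetrize by
#' averaging with the transpose, and set the diagonal to 1.  Each row is
#' diagonally dominant before symmetrization; averaging can break dominance
#' at hub nodes with many low-degree neighbours, so in the rare case the
#' averaged matrix is not comfortably positive definite its off-diagonal
#' block is shrunk uniformly until the smallest eigenvalue is 0.01.  The
#' shrinkage preserves the sparsity pattern, so features can be drawn from
#' \eqn{MVN(0, \Omega^{-1})} with conditional independence exactly matching
#' the non-edges.
#'
#' @param g A [pathway_graph()].
#' @return A symmetric positive definite p x p matrix.
#' @export
precision_from_adjacency <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  a <- adjacency_matrix(g)
  rs <- rowSums(abs(a))
  scal <- ifelse(rs > 0, 1 / (1.5 * rs), 0)
  om <- a * scal
  om <- (om + t(om)) / 2
  diag(om) <- 1
  lmin <- min(eigen(om, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < 0.01) {
    shrink <- (1 - lmin) / 0.99
    om <- om / shrink
    diag(om) <- 1
  }
  om
}

#' Draw multivariate normal features from a precision matrix
#'
#' n iid rows from \eqn{MVN(0, \Omega^{-1})}.
#'
#' @param omega Symmetric positive definite precision matrix.
#' @param n Number of samples.
#' @inheritParams sample_ba_graph
#' @return n x p matrix with the precision matrix's dimnames as column
#'   names and sample ids `s1 ... sn` as rownames.
#' @export
sample_features <- function(omega, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(omega)
  ch <- tryCatch(chol(omega), error = function(e) {
    stop("`omega` is not positive definite")
  })
  sigma <- chol2inv(ch)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
  dimnames(z) <- list(paste0("s", seq_len(n)), colnames(omega))
  z
}

#' Simulate a continuous outcome from features
#'
#' \eqn{Y_i = 0.26 + 0.5 X_{1i} + 0.25 X_{2i} + \sum_j \beta_j Z_{ij} +
#' \epsilon_i}, with \eqn{X_1 \sim Bernoulli(0.5)}, \eqn{X_2 \sim U(0,1)}
#' and \eqn{\epsilon \sim N(0, 1.3688^2)} (residual standard deviation
#' calibrated to observed metabolomics data).  `beta_effect = 0` gives the
#' null; 0.1 is the reference alternative.
#'
#' @param z n x p feature matrix.
#' @param beta_effect Common coefficient applied to every feature column, or
#'   a length-p vector of coefficients.
#' @param sigma Residual standard deviation.
#' @inheritParams sample_ba_graph
#' @return List with `y` (length-n outcome) and `x` (n x 3 design matrix:
#'   intercept, x1, x2).
#' @export
sample_outcome <- function(z, beta_effect = 0, sigma = 1.3688, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- as.matrix(z)
  n <- nrow(z)
  beta <- if (length(beta_effect) == 1L) {
    rep(beta_effect, ncol(z))
  } else {
    stopifnot(length(beta_effect) == ncol(z))
    beta_effect
  }
  x1 <- stats::rbinom(n, 1L, 0.5)
  x2 <- stats::runif(n)
  y <- 0.26 + 0.5 * x1 + 0.25 * x2 + drop(z %*% beta) +
    stats::rnorm(n, 0, sigma)
  list(y = y,
       x = cbind("(Intercept)" = 1, x1 = x1, x2 = x2))
}

#' Randomly drop weakly connected nodes
#'
#' Emulates incomplete measurement: each weakly connected node -- degree at
#' or below the 25th percentile of the degree sequence
#' (linear-interpolation quantile), excluding nodes of maximal degree -- is
#' removed independently with probability 0.25.  Excluding the maximal
#' degree means a regular graph, where no node is better connected than any
#' other, loses nothing; in scale-free trees the rule targets the leaves.
#' The caller drops the matching feature columns.
#'
#' @param g A [pathway_graph()] with at least 4 nodes.
#' @inheritParams sample_ba_graph
#' @return List with `graph` (the induced subgraph) and `kept` (surviving
#'   node labels, in the original order).
#' @export
drop_low_degree_nodes <- function(g, seed = NULL) {
  stopifnot(inherits(g, "pathway_graph"))
  if (n_nodes(g) < 4L) stop("need at least 4 nodes")
  if (!is.null(seed)) set.seed(seed)
  deg <- graph_degrees(g)
  q25 <- stats::quantile(deg, 0.25, names = FALSE)  # type 7: linear interp
  eligible <- deg <= q25 & deg < max(deg)
  drop <- eligible & (stats::runif(length(deg)) < 0.25)
  kept <- g$nodes[!drop]
  list(graph = restrict_to_measured(g, kept), kept = kept)
}

edge_key <- function(idx) paste(idx[, 1L], idx[, 2L])

#' Randomly rewire a fraction of edges
#'
#' Each edge is independently selected with probability `frac`; a selected
#' edge {u, v} is replaced by {u, w}, with w drawn uniformly from the nodes
#' for which {u, w} is neither a current edge, an edge of the original
#' graph, nor a self-loop.  Edge count is preserved, and at `frac = 1` the
#' result shares no edge with the input (unless no legal replacement
#' exists, in which case the edge is left in place and counted in the
#' `n_unresolved` attribute).
#'
#' @param g A [pathway_graph()].
#' @param frac Per-edge rewiring probability in \[0, 1\].
#' @inheritParams sample_ba_graph
#' @return A [pathway_graph()] with the same nodes and edge count.
#' @export
rewire_edges <- function(g, frac, seed = NULL) {
  stopifnot(inherits(g, "pathway_graph"), frac >= 0, frac <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- n_nodes(g)
  a <- adjacency_matrix(g)
  orig <- a
  edges <- g$edges  # canonical order
  unresolved <- 0L
  for (i in seq_len(nrow(edges))) {
    if (stats::runif(1L) >= frac) next
    u <- edges[i, 1L]; v <- edges[i, 2L]
    cand <- which(a[u, ] == 0 & orig[u, ] == 0 & seq_len(p) != u)
    if (!length(cand)) {
      unresolved <- unresolved + 1L
      next
    }
    w <- cand[sample.int(length(cand), 1L)]
    a[u, v] <- a[v, u] <- 0
    a[u, w] <- a[w, u] <- 1
    edges[i, ] <- c(min(u, w), max(u, w))
  }
  out <- pathway_graph(g$nodes, cbind(g$nodes[edges[, 1L]],
                                      g$nodes[edges[, 2L]]))
  attr(out, "n_unresolved") <- unresolved
  out
}

#' Edge-disjoint replacement graph
#'
#' Draws a fresh scale-free tree on the same node labels and rewires any
#' edge it shares with `g` until the two graphs have no edge in common: the
#' "complete mismatch" structure scenario.
#'
#' @param g A [pathway_graph()].
#' @param max_tries Bound on rewiring passes before giving up.
#' @inheritParams sample_ba_graph
#' @return A [pathway_graph()] on `g$nodes` with `p - 1` edges and empty
#'   edge intersection with `g`.
#' @export
disjoint_edge_graph <- function(g, seed = NULL, max_tries = 1e4) {
  stopifnot(inherits(g, "pathway_graph"))
  if (!is.null(seed)) set.seed(seed)
  p <- n_nodes(g)
  forbidden <- adjacency_matrix(g)
  g2 <- sample_ba_graph(p)
  g2 <- pathway_graph(g$nodes, cbind(g$nodes[g2$edges[, 1L]],
                                     g$nodes[g2$edges[, 2L]]))
  a <- adjacency_matrix(g2)
  edges <- g2$edges
  tries <- 0L
  repeat {
    clash <- which(forbidden[edges] > 0)
    if (!length(clash)) break
    for (i in clash) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(structure(
          class = c("netkat_generation_error", "error", "condition"),
          list(message = "could not build an edge-disjoint graph",
               call = sys.call(-1))))
      }
      u <- edges[i, 1L]; v <- edges[i, 2L]
      cand <- which(a[u, ] == 0 & forbidden[u, ] == 0 & seq_len(p) != u)
      if (!length(cand)) next
      w <- cand[sample.int(length(cand), 1L)]
      a[u, v] <- a[v, u] <- 0
      a[u, w] <- a[w, u] <- 1
      edges[i, ] <- c(min(u, w), max(u, w))
    }
  }
  pathway_graph(g$nodes, cbind(g$nodes[edges[, 1L]], g$nodes[edges[, 2L]]))
}

#' Signal-to-noise ratio of a simulated outcome
#'
#' Ratio of the variance of the structured mean component,
#' \eqn{Var(\sum_j \beta_j Z_{ij}) = \beta' \Omega^{-1} \beta}, to the
#' residual variance of the outcome about that component,
#' \eqn{Var(0.5 X_1 + 0.25 X_2 + \epsilon)}.  Under the default covariate
#' distributions the denominator is \eqn{0.25 \cdot 0.25 + 0.0625/12 +
#' \sigma^2}; set `include_covariates = FALSE` for the sigma^2-only variant.
#'
#' @param beta Length-p coefficient vector.
#' @param omega Precision matrix of the features.
#' @param sigma2 Residual variance of the outcome noise.
#' @param include_covariates Include the covariate terms in the denominator.
#' @return Nonnegative scalar.
#' @export
signal_to_noise <- function(beta, omega, sigma2 = 1.3688^2,
                            include_covariates = TRUE) {
  stopifnot(length(beta) == nrow(omega))
  num <- drop(crossprod(beta, solve(omega, beta)))
  den <- if (include_covariates) {
    0.25 * 0.25 + 0.0625 * (1 / 12) + sigma2
  } else {
    sigma2
  }
  num / den
}

#' Small synthetic dataset for examples
#'
#' Generates a feature table, covariate table and a two-pathway definition
#' from the package's own simulation model, for use in examples and smoke
#' tests.
#'
#' @param n,p Samples and features.
#' @param beta_effect Per-feature effect on the outcome.
#' @param seed RNG seed.
#' @return List with `features`, `covariates` (tibbles, first column
#'   `sample_id`), and `pathways` (named list of [pathway_graph()]).
#' @export
demo_pathway_data <- function(n = 60, p = 8, beta_effect = 0, seed = 1) {
  set.seed(seed)
  g <- sample_ba_graph(p)
  z <- sample_features(precision_from_adjacency(g), n)
  out <- sample_outcome(z, beta_effect)
  half <- seq_len(floor(p / 2))
  pw <- list(
    pw_all = g,
    pw_half = restrict_to_measured(g, g$nodes[half]))
  feats <- tibble::as_tibble(z)
  feats <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(z)), feats)
  covs <- tibble::tibble(sample_id = rownames(z), y = out$y,
                         x1 = out$x[, "x1"], x2 = out$x[, "x2"])
  list(features = feats, covariates = covs, pathways = pw)
}
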