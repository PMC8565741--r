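#' Construct a pathway graph
#'
#' A pathway graph is an undirected, unweighted graph over an ordered set of
#' feature labels (metabolites, proteins, genes).  Node order is significant:
#' every matrix derived from the graph (adjacency, Laplacians) uses this
#' order, and feature matrices must align their columns with it.
#'
#' @param nodes Character vector of unique node labels, in the order they
#'   appear in the pathway definition.
#' @param edges Edges as a two-column matrix or data frame of node labels, or
#'   `NULL`/zero rows for an edgeless graph.  `{u,v}` and `{v,u}` are the same
#'   edge; duplicates are collapsed.  Self-loops are rejected.
#'
#' @return An object of class `pathway_graph` with elements `nodes` (ordered
#'   labels) and `edges` (an integer matrix of node indices, one row per
#'   edge, first index smaller).
#' @examples
#' g <- pathway_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' count_components(g)
#' @export
pathway_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node labels: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    idx <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("`edges` must have two columns")
    u <- match(as.character(edges[, 1L]), nodes)
    v <- match(as.character(edges[, 2L]), nodes)
    bad <- is.na(u) | is.na(v)
    if (any(bad)) {
      unknown <- setdiff(as.character(edges[bad, , drop = FALSE]), nodes)
      stop("edge endpoint(s) not in `nodes`: ",
           paste(unique(unknown), collapse = ", "))
    }
    if (any(u == v)) {
      stop("self-loops are not allowed (node ",
           nodes[u[which(u == v)[1L]]], ")")
    }
    idx <- cbind(pmin(u, v), pmax(u, v))
    idx <- idx[!duplicated(idx), , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = idx), class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", count_components(x), " component(s)\n", sep = "")
  invisible(x)
}

n_nodes <- function(g) length(g$nodes)
n_edges <- function(g) nrow(g$edges)

#' Adjacency matrix of a pathway graph
#'
#' @param g A [pathway_graph()].
#' @return A symmetric 0/1 matrix with zero diagonal, dimnames `g$nodes`.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  p <- n_nodes(g)
  a <- matrix(0, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    a[g$edges] <- 1
    a[g$edges[, 2:1, drop = FALSE]] <- 1
  }
  a
}

graph_degrees <- function(g) {
  a <- adjacency_matrix(g)
  rowSums(a)
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_nodes(g), directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, as.vector(t(g$edges)))
  ig
}

#' Normalized graph Laplacian
#'
#' Computes \eqn{\tilde L = I - D^{-1/2} A D^{-1/2}} on nodes with at least
#' one edge.  For an isolated (degree-0) node the corresponding row and
#' column are set to zero, so each isolated node contributes a zero
#' eigenvalue and the regularized Laplacian acts as the identity on it.  With
#' this convention an edgeless pathway makes the pathway-integrated test
#' reduce exactly to the pathway-free test.
#'
#' \eqn{\tilde L} is symmetric positive semidefinite with eigenvalues in
#' \[0, 2\]; the multiplicity of eigenvalue 0 equals the number of connected
#' components (isolated nodes counting as components).
#'
#' @param g A [pathway_graph()].
#' @return A symmetric p x p matrix with attribute `kind = "normalized"`.
#' @export
normalized_laplacian <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  a <- adjacency_matrix(g)
  d <- rowSums(a)
  isq <- ifelse(d > 0, 1 / sqrt(d), 0)
  l <- -a * tcrossprod(isq)
  diag(l) <- as.numeric(d > 0)
  l <- (l + t(l)) / 2
  attr(l, "kind") <- "normalized"
  l
}

#' Regularized normalized Laplacian
#'
#' Applies the linear regularization \eqn{\tilde L_R = (I + \tau \tilde
#' L)^{-1}}.  Its eigenvalues are \eqn{1/(1 + \tau \lambda_i)}, a monotone
#' decreasing map of the Laplacian spectrum: high-frequency (noisy) graph
#' components are shrunk while low-frequency structure, including
#' disconnected nodes (\eqn{\lambda = 0}), is preserved at weight 1.  The
#' result is symmetric positive definite with eigenvalues in
#' \eqn{[1/(1+2\tau), 1]}.
#'
#' @param lnorm A normalized Laplacian matrix (from
#'   [normalized_laplacian()]).
#' @param tau Nonnegative smoothing bandwidth; `tau = 0` returns the
#'   identity.
#' @return A symmetric p x p matrix with attributes `kind = "regularized"`
#'   and `tau`.
#' @export
regularize_laplacian <- function(lnorm, tau = 1) {
  if (!is.matrix(lnorm) || nrow(lnorm) != ncol(lnorm)) {
    stop("`lnorm` must be a square matrix")
  }
  if (!isTRUE(all.equal(lnorm, t(lnorm), tolerance = 1e-10,
                        check.attributes = FALSE))) {
    stop("`lnorm` must be symmetric")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("`tau` must be a single nonnegative number")
  }
  p <- nrow(lnorm)
  ev <- eigen(lnorm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev))) {
    stop("`lnorm` is not positive semidefinite; not a valid normalized Laplacian")
  }
  m <- diag(p) + tau * lnorm
  lr <- chol2inv(chol(m))
  lr <- (lr + t(lr)) / 2
  dimnames(lr) <- dimnames(lnorm)
  attr(lr, "kind") <- "regularized"
  attr(lr, "tau") <- tau
  lr
}

#' Number of connected components
#'
#' Each isolated node counts as its own component.  Equals the multiplicity
#' of the zero eigenvalue of the normalized Laplacian.
#'
#' @param g A [pathway_graph()].
#' @return Nonnegative integer.
#' @export
count_components <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  if (n_nodes(g) == 0L) return(0L)
  igraph::components(as_igraph(g))$no
}

#' Restrict a pathway graph to measured features
#'
#' Returns the induced subgraph on the nodes that were actually measured,
#' preserving node order; edges with a dropped endpoint are removed.  Real
#' datasets rarely measure every member of a curated pathway, so graphs are
#' restricted before any Laplacian computation.
#'
#' @param g A [pathway_graph()].
#' @param measured Character vector of measured feature labels.
#' @return A [pathway_graph()] on `intersect(g$nodes, measured)` in the
#'   original node order.
#' @export
restrict_to_measured <- function(g, measured) {
  stopifnot(inherits(g, "pathway_graph"))
  keep <- g$nodes %in% measured
  if (!any(keep)) {
    stop(structure(
      class = c("netkat_empty_pathway", "error", "condition"),
      list(message = "no pathway member was measured; pathway is empty",
           call = sys.call(-1))))
  }
  kept <- g$nodes[keep]
  if (nrow(g$edges)) {
    lab <- cbind(g$nodes[g$edges[, 1L]], g$nodes[g$edges[, 2L]])
    lab <- lab[lab[, 1L] %in% kept & lab[, 2L] %in% kept, , drop = FALSE]
  } else {
    lab <- NULL
  }
  pathway_graph(kept, lab)
}
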