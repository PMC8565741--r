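#' Project a feature matrix through a graph regularizer
#'
#' Computes `z %*% lr`, replacing each feature by a smoothness-weighted
#' combination of its pathway neighbours.  With the identity regularizer
#' (`tau = 0`, or an edgeless graph) the features are returned unchanged.
#'
#' @param z Numeric n x p matrix of features, columns aligned with the graph
#'   node order.
#' @param lr p x p regularized Laplacian from [regularize_laplacian()] (or
#'   the normalized Laplacian, for the unregularized variant).
#' @return n x p matrix with the same dimnames as `z`.
#' @export
project_features <- function(z, lr) {
  z <- as.matrix(z)
  if (ncol(z) != nrow(lr)) {
    stop("`z` has ", ncol(z), " columns but `lr` is ", nrow(lr), " x ",
         ncol(lr))
  }
  if (!is.null(colnames(z)) && !is.null(rownames(lr)) &&
      !identical(colnames(z), rownames(lr))) {
    stop("feature labels of `z` do not match the node order of `lr`")
  }
  out <- z %*% lr
  dimnames(out) <- dimnames(z)
  out
}

#' Median-heuristic kernel bandwidth
#'
#' The Gaussian kernel bandwidth rho is set to the median of the n(n-1)/2
#' pairwise Euclidean distances between sample rows (the median heuristic).
#' A squared-distance variant is available for users who prefer that
#' convention.
#'
#' @param z Numeric n x p matrix (n >= 2), normally the projected features.
#' @param method `"median_dist"` (default) for the median distance,
#'   `"median_sqdist"` for the median squared distance.
#' @return A positive scalar.
#' @export
median_bandwidth <- function(z, method = c("median_dist", "median_sqdist")) {
  method <- match.arg(method)
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least two samples to estimate a bandwidth")
  d <- stats::dist(z)
  rho <- if (method == "median_dist") stats::median(d) else stats::median(d^2)
  if (!is.finite(rho) || rho <= .Machine$double.eps) {
    stop("degenerate data: median pairwise distance is zero")
  }
  rho
}

pairwise_sqdist <- function(z) {
  # stable expansion ||zi - zj||^2 = ||zi||^2 + ||zj||^2 - 2<zi, zj>
  s <- rowSums(z^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(z)
  d2[d2 < 0] <- 0
  d2
}

#' Gaussian kernel matrix
#'
#' `K[i, j] = exp(-||z_i - z_j||^2 / rho)`.  Symmetric with unit diagonal
#' and positive semidefinite.
#'
#' @param z Numeric n x p matrix.
#' @param rho Positive bandwidth, usually from [median_bandwidth()].
#' @return n x n kernel matrix with attributes `bandwidth` and
#'   `kernel = "gaussian"`.
#' @export
gaussian_kernel <- function(z, rho) {
  z <- as.matrix(z)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("`rho` must be a single positive number")
  }
  k <- exp(-pairwise_sqdist(z) / rho)
  diag(k) <- 1
  k <- (k + t(k)) / 2
  attr(k, "bandwidth") <- rho
  attr(k, "kernel") <- "gaussian"
  k
}

#' Linear and polynomial kernels
#'
#' Alternative kernels behind the same interface as [gaussian_kernel()].
#' The association test machinery accepts any symmetric positive
#' semidefinite kernel; all calibration work in this package uses the
#' Gaussian kernel.
#'
#' @param z Numeric n x p matrix.
#' @param rho Offset of the polynomial kernel.
#' @param degree Degree of the polynomial kernel.
#' @return n x n kernel matrix.
#' @export
linear_kernel <- function(z) {
  k <- tcrossprod(as.matrix(z))
  attr(k, "kernel") <- "linear"
  k
}

#' @rdname linear_kernel
#' @export
polynomial_kernel <- function(z, rho = 1, degree = 2) {
  k <- (tcrossprod(as.matrix(z)) + rho)^degree
  attr(k, "kernel") <- "polynomial"
  attr(k, "bandwidth") <- rho
  k
}
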