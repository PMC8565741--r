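#' Fit the null (covariates-only) linear model
#'
#' Ordinary least squares of the outcome on the covariates alone.  The
#' kernel score test is a variance-component score test: it only ever needs
#' this null fit, never an estimate of the kernel effect itself.  The fit is
#' computed once and reused across all pathways.
#'
#' @param y Numeric outcome vector of length n.
#' @param x n x q numeric design matrix including the intercept column; must
#'   have full column rank with n > q.
#' @return An object of class `netkat_null` with elements `residuals`,
#'   `sigma2` (residual variance, rss / (n - q)), `n`, `q`, `fitted`, and the
#'   QR decomposition used to apply the residual projection.
#' @export
fit_null <- function(y, x) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  n <- length(y)
  q <- ncol(x)
  if (nrow(x) != n) stop("`y` and `x` have different numbers of rows")
  if (n <= q) stop("need more observations than covariates (n > q)")
  qx <- qr(x)
  if (qx$rank < q) stop("`x` is rank deficient; drop collinear covariates")
  r <- qr.resid(qx, y)
  sigma2 <- sum(r^2) / (n - q)
  structure(
    list(residuals = r, sigma2 = sigma2, n = n, q = q,
         fitted = y - r, qr = qx),
    class = "netkat_null")
}

#' @export
print.netkat_null <- function(x, ...) {
  cat("<netkat_null> n = ", x$n, ", q = ", x$q,
      ", sigma2 = ", format(x$sigma2, digits = 4), "\n", sep = "")
  invisible(x)
}

# apply the residual projection P0 = I - X (X'X)^-1 X' to the columns of m
project_residual <- function(nf, m) {
  qr.resid(nf$qr, m)
}
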