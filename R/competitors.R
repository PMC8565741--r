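#' Principal-component F-test for a feature set
#'
#' Fits the outcome on the covariates plus all principal-component scores of
#' the column-centered feature matrix, and F-tests that block against the
#' covariates-only model.  Because the PCs span the full column space of the
#' centered features, the p-value is invariant to any invertible linear
#' transformation of the features; in particular it is identical on Z and on
#' the Laplacian-projected Z.
#'
#' @param y Numeric outcome vector.
#' @param x n x q design matrix including the intercept.
#' @param z n x p numeric feature matrix.
#' @return The F-test p-value (scalar in \[0, 1\]).
#' @export
pc_f_test <- function(y, x, z) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  z <- as.matrix(z)
  n <- length(y)
  q <- ncol(x)
  if (n <= q + ncol(z)) {
    stop("too few observations for the full-rank fit (need n > q + p)")
  }
  zc <- scale(z, center = TRUE, scale = FALSE)
  pcs <- stats::prcomp(zc, center = FALSE)$x
  keep <- which(apply(pcs, 2L, stats::sd) > 1e-10 * max(stats::sd(pcs), 1e-300))
  pcs <- pcs[, keep, drop = FALSE]
  r <- length(keep)
  if (r == 0L) stop("feature matrix has no variation")
  q0 <- qr(x)
  rss0 <- sum(qr.resid(q0, y)^2)
  q1 <- qr(cbind(x, pcs))
  if (q1$rank < q + r) stop("combined design is rank deficient")
  rss1 <- sum(qr.resid(q1, y)^2)
  df2 <- n - q - r
  f <- ((rss0 - rss1) / r) / (rss1 / df2)
  stats::pf(f, r, df2, lower.tail = FALSE)
}

#' Minimum Simes-adjusted univariate p-value
#'
#' Fits one covariate-adjusted linear model per feature column, takes the
#' two-sided p-value for that feature's coefficient, and combines the p
#' per-feature p-values with Simes' procedure:
#' \eqn{\min_i \{ p \cdot p_{(i)} / i \}}, capped at 1.
#'
#' @inheritParams pc_f_test
#' @return The Simes-combined p-value (scalar in \[0, 1\]).
#' @export
univariate_simes <- function(y, x, z) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  z <- as.matrix(z)
  n <- length(y)
  q <- ncol(x)
  if (n <= q + 1L) stop("too few observations (need n > q + 1)")
  q0 <- qr(x)
  ry <- qr.resid(q0, y)
  rz <- qr.resid(q0, z)
  df <- n - q - 1L
  pv <- vapply(seq_len(ncol(z)), function(j) {
    ssz <- sum(rz[, j]^2)
    if (ssz <= 1e-12 * max(1, sum(z[, j]^2))) {
      warning("feature column ", j,
              " is constant given the covariates; its p-value is set to 1")
      return(1)
    }
    bhat <- sum(rz[, j] * ry) / ssz
    rss <- sum(ry^2) - bhat^2 * ssz
    se <- sqrt(max(rss, 0) / df / ssz)
    if (se == 0) return(0)
    2 * stats::pt(-abs(bhat / se), df)
  }, numeric(1L))
  simes_pvalue(pv)
}

# Simes global p-value: min_i { m p_(i) / i }, capped at 1
simes_pvalue <- function(pv) {
  m <- length(pv)
  ps <- sort(pv)
  min(1, min(m * ps / seq_len(m)))
}
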