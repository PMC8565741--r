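#' Quadratic kernel score statistic
#'
#' The variance-component score statistic \eqn{Q = r' K r / \hat\sigma^2},
#' where r are the null-model residuals.  Under the null, Q is a weighted
#' sum of chi-square variables; p-values are computed by
#' [kernel_test_pvalue()], which uses an exact small-sample ratio form
#' rather than this raw statistic.
#'
#' @param nf A [fit_null()] object.
#' @param k n x n kernel matrix.
#' @return Nonnegative scalar.
#' @export
score_statistic <- function(nf, k) {
  stopifnot(inherits(nf, "netkat_null"))
  if (nrow(k) != nf$n || ncol(k) != nf$n) {
    stop("kernel matrix dimension does not match the null fit")
  }
  if (nf$sigma2 < 1e-12) {
    stop("degenerate residual variance (sigma2 < 1e-12); outcome is fit exactly by the covariates")
  }
  r <- nf$residuals
  drop(crossprod(r, k %*% r)) / nf$sigma2
}

#' Tail probability of a weighted sum of chi-square variables
#'
#' Computes \eqn{P(\sum_i w_i \xi_i > t)} for iid \eqn{\xi_i \sim \chi^2_1},
#' with arbitrary (possibly negative) weights, by numerical inversion of the
#' characteristic function (the Gil-Pelaez / Davies integral).  When all
#' nonzero weights are equal the scaled chi-square result is returned
#' exactly.  If the numerical integration fails to converge, a
#' moment-matching (Liu-type) approximation is used instead and flagged.
#'
#' @param weights Numeric vector, not all zero.
#' @param t Threshold.
#' @return A list with `p` (the tail probability, clipped to \[0, 1\]) and
#'   `davies_converged` (logical; `FALSE` when the fallback was used).
#' @export
weighted_chisq_tail <- function(weights, t) {
  w <- weights[weights != 0]
  if (!length(w)) stop("`weights` must contain a nonzero entry")
  # all equal weights: exact scaled chi-square
  if (max(w) - min(w) <= 1e-14 * max(abs(w))) {
    c1 <- w[1L]
    p <- if (c1 > 0) {
      stats::pchisq(t / c1, df = length(w), lower.tail = FALSE)
    } else {
      stats::pchisq(t / c1, df = length(w), lower.tail = TRUE)
    }
    return(list(p = p, davies_converged = TRUE))
  }
  res <- davies_tail(w, t)
  if (res$converged && res$p > -1e-6 && res$p < 1 + 1e-6) {
    list(p = min(max(res$p, 0), 1), davies_converged = TRUE)
  } else {
    list(p = liu_tail(w, t), davies_converged = FALSE)
  }
}

# Gil-Pelaez inversion: P(Q > t) = 1/2 + (1/pi) int_0^inf
#   Im[e^{-iut} phi(u)] / u du, phi(u) = prod_j (1 - 2 i w_j u)^{-1/2}.
# In polar form the integrand is R(u) sin(theta(u) - t u) / u with
#   R(u) = exp(-1/4 sum log(1 + 4 w^2 u^2)),
#   theta(u) = 1/2 sum atan(2 w u).
davies_tail <- function(w, t) {
  integrand <- function(u) {
    wu <- outer(w, u)
    th <- 0.5 * colSums(atan(2 * wu))
    lr <- 0.25 * colSums(log1p(4 * wu^2))
    out <- exp(-lr) * sin(th - t * u) / u
    out[u == 0] <- sum(w) - t
    out
  }
  res <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12,
                     subdivisions = 5000L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) {
    return(list(p = NA_real_, converged = FALSE))
  }
  list(p = 0.5 + res$value / pi, converged = res$abs.error < 1e-4)
}

# Liu-Tang-Zhang moment-matching approximation to the same tail probability
liu_tail <- function(w, t) {
  c1 <- sum(w); c2 <- sum(w^2); c3 <- sum(w^3); c4 <- sum(w^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  tstar <- (t - c1) / sqrt(2 * c2)
  q <- tstar * sqrt(2 * (l + 2 * delta)) + l + delta
  stats::pchisq(q, df = l, ncp = delta, lower.tail = FALSE)
}

#' Small-sample kernel association p-value
#'
#' Exact finite-sample form of the kernel score test for Gaussian errors.
#' Rather than plugging the residual-variance estimate into the raw
#' statistic (unstable at small n), the test conditions it out through the
#' ratio \eqn{s = r'Kr / r'r}.  Writing \eqn{P_0} for the residual
#' projection and \eqn{\lambda_1, \ldots, \lambda_m} (m = n - q) for the
#' residual-space eigenvalues of \eqn{P_0 K P_0},
#' \deqn{P(s^{obs} < s) = P\left(\sum_i (\lambda_i - s)\,\xi_i > 0\right),
#'   \quad \xi_i \sim \chi^2_1,}
#' which is evaluated with [weighted_chisq_tail()] at t = 0.
#'
#' @param nf A [fit_null()] object.
#' @param k n x n symmetric positive semidefinite kernel matrix.
#' @return A list with `statistic` (the raw quadratic score statistic
#'   \eqn{r'Kr/\hat\sigma^2}), `p_value`, and `davies_converged`.
#' @export
kernel_test_pvalue <- function(nf, k) {
  stopifnot(inherits(nf, "netkat_null"))
  if (nrow(k) != nf$n || ncol(k) != nf$n) {
    stop("kernel matrix dimension does not match the null fit")
  }
  if (nf$sigma2 < 1e-12) {
    stop("degenerate residual variance (sigma2 < 1e-12)")
  }
  r <- nf$residuals
  m <- nf$n - nf$q
  s <- drop(crossprod(r, k %*% r)) / sum(r^2)
  pkp <- project_residual(nf, t(project_residual(nf, k)))
  pkp <- (pkp + t(pkp)) / 2
  ev <- eigen(pkp, symmetric = TRUE, only.values = TRUE)$values
  lam <- ev[seq_len(m)]
  lam[abs(lam) < 1e-8 * max(abs(lam[1L]), .Machine$double.xmin)] <- 0
  wts <- lam - s
  statistic <- s * m
  if (max(abs(wts)) <= 1e-10 * max(1, abs(s))) {
    warning("kernel is proportional to the identity on the residual space; ",
            "it carries no contrast and the test is uninformative (p = 1)")
    return(list(statistic = statistic, p_value = 1, davies_converged = TRUE))
  }
  tail <- weighted_chisq_tail(wts, 0)
  list(statistic = statistic, p_value = tail$p,
       davies_converged = tail$davies_converged)
}
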