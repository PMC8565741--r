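#' Pathway association tests for a feature table
#'
#' Runs a pathway-by-pathway association test between a continuous outcome
#' and measured molecular features, optionally injecting pathway topology
#' into the Gaussian kernel through the regularized normalized Laplacian.
#' The semiparametric model is \eqn{Y = X\beta + h(Z \tilde L_R) + \epsilon};
#' association is assessed with a variance-component score test that only
#' requires the covariates-only null fit, with p-values from an exact
#' small-sample ratio form evaluated by characteristic-function inversion.
#'
#' Modes:
#' \describe{
#'   \item{`pairkat`}{Gaussian kernel on `Z %*% LR`, `LR = (I + tau * L)^-1`
#'     (the pathway-integrated test).}
#'   \item{`laplacian`}{Gaussian kernel on `Z %*% L` (unregularized).}
#'   \item{`none`}{Gaussian kernel on raw Z; pathway topology ignored.}
#'   \item{`pc_ftest`}{F-test on all principal components of Z.}
#'   \item{`simes`}{minimum Simes-adjusted univariate p-value.}
#' }
#'
#' @param features Data frame whose first column holds sample identifiers and
#'   whose remaining columns are numeric feature abundances (samples in
#'   rows), e.g. from [read_feature_table()]; or a numeric matrix with sample
#'   identifiers as rownames.
#' @param covariates Data frame whose first column holds sample identifiers,
#'   containing the outcome column named by `outcome` plus the adjustment
#'   covariates.  Character/factor covariates are expanded through
#'   [stats::model.matrix()]; an intercept is always included.
#' @param outcome Name of the outcome column in `covariates`.
#' @param pathways Pathway definitions from [read_pathways()], or a named
#'   list of [pathway_graph()] objects.
#' @param mode Test variant; see Details.
#' @param tau Laplacian smoothing bandwidth (default 1).
#' @param bandwidth Kernel bandwidth rule, see [median_bandwidth()].
#' @param adjust If `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column across the tested pathways.
#' @param standardize If `TRUE`, z-score each feature column before testing.
#'   Off by default: features are expected to arrive already normalized.
#' @return An object of class `kat_test`; `tidy()` returns a tibble with one
#'   row per tested pathway (columns `pathway_id`, `mode`, `n_nodes_used`,
#'   `n_components`, `rho`, `tau`, `statistic`, `p_value`,
#'   `davies_converged`), `glance()` a one-row model summary, and
#'   `autoplot()` a p-value dot plot.  Pathways with fewer than two measured
#'   members are skipped with a warning and listed in `$skipped`.
#' @examples
#' sim <- demo_pathway_data(n = 40, p = 6, seed = 1)
#' fit <- kat_test(sim$features, sim$covariates, "y", sim$pathways)
#' tidy(fit)
#' @export
kat_test <- function(features, covariates, outcome, pathways,
                     mode = c("pairkat", "laplacian", "none",
                              "pc_ftest", "simes"),
                     tau = 1,
                     bandwidth = c("median_dist", "median_sqdist"),
                     adjust = FALSE, standardize = FALSE) {
  mode <- match.arg(mode)
  bandwidth <- match.arg(bandwidth)
  z <- as_feature_matrix(features)
  cv <- as.data.frame(covariates)
  if (ncol(cv) < 2L) stop("`covariates` needs a sample-id column plus data columns")
  ids <- as.character(cv[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in `covariates`")
  if (!outcome %in% names(cv)) {
    stop("outcome column '", outcome, "' not found in `covariates`")
  }
  common <- intersect(rownames(z), ids)
  if (length(common) < 3L) {
    stop("fewer than 3 samples shared between `features` and `covariates`")
  }
  z <- z[common, , drop = FALSE]
  cv <- cv[match(common, ids), , drop = FALSE]
  y <- as.numeric(cv[[outcome]])
  xdf <- cv[, setdiff(names(cv)[-1L], outcome), drop = FALSE]
  x <- if (ncol(xdf)) {
    stats::model.matrix(~., data = xdf)
  } else {
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  if (standardize) z <- scale(z)
  graphs <- as_pathway_list(pathways)
  nf <- fit_null(y, x)

  rows <- list(); skipped <- character(0)
  for (pid in names(graphs)) {
    g <- tryCatch(restrict_to_measured(graphs[[pid]], colnames(z)),
                  netkat_empty_pathway = function(e) NULL)
    if (is.null(g) || n_nodes(g) < 2L) {
      warning("pathway '", pid, "' has fewer than 2 measured members; skipped")
      skipped <- c(skipped, pid)
      next
    }
    zg <- z[, g$nodes, drop = FALSE]
    rows[[pid]] <- test_one_pathway(nf, zg, g, mode, tau, bandwidth, pid)
  }
  results <- dplyr::bind_rows(rows)
  if (adjust && nrow(results)) {
    results$p_adjusted <- stats::p.adjust(results$p_value, method = "BH")
  }
  structure(
    list(results = results, skipped = skipped, mode = mode, tau = tau,
         bandwidth = bandwidth, n = nf$n, q = nf$q, sigma2 = nf$sigma2,
         outcome = outcome),
    class = "kat_test")
}

# one pathway, matrices already aligned
test_one_pathway <- function(nf, zg, g, mode, tau, bandwidth, pid) {
  rho <- NA_real_
  if (mode %in% c("pairkat", "laplacian", "none")) {
    zp <- switch(mode,
      pairkat   = project_features(zg, regularize_laplacian(
                    normalized_laplacian(g), tau)),
      laplacian = project_features(zg, normalized_laplacian(g)),
      none      = zg)
    rho <- median_bandwidth(zp, bandwidth)
    res <- kernel_test_pvalue(nf, gaussian_kernel(zp, rho))
    stat <- res$statistic; pval <- res$p_value; conv <- res$davies_converged
  } else {
    pval <- switch(mode,
      pc_ftest = pc_f_test(nf$fitted + nf$residuals,
                           qr.X(nf$qr), zg),
      simes    = univariate_simes(nf$fitted + nf$residuals,
                                  qr.X(nf$qr), zg))
    stat <- NA_real_; conv <- NA
  }
  tibble::tibble(
    pathway_id = pid, mode = mode,
    n_nodes_used = n_nodes(g), n_components = count_components(g),
    rho = rho, tau = if (mode == "pairkat") tau else NA_real_,
    statistic = stat, p_value = pval, davies_converged = conv)
}

#' @export
print.kat_test <- function(x, ...) {
  cat("<kat_test> mode = ", x$mode, ", n = ", x$n, ", ",
      nrow(x$results), " pathway(s) tested",
      if (length(x$skipped)) paste0(", ", length(x$skipped), " skipped"),
      "\n", sep = "")
  print(x$results)
  invisible(x)
}

# coerce a feature table (first column sample ids) or matrix to a matrix
as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (is.null(rownames(features))) {
      stop("feature matrix needs sample identifiers as rownames")
    }
    storage.mode(features) <- "double"
    return(features)
  }
  df <- as.data.frame(features)
  if (ncol(df) < 2L) stop("feature table needs a sample-id column plus features")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in feature table")
  z <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(z) <- "double"
  if (anyNA(z)) {
    stop("feature table contains missing values; impute upstream before testing")
  }
  rownames(z) <- ids
  z
}

# pathways: kat_pathways tibble or named list of pathway_graph
as_pathway_list <- function(pathways) {
  if (inherits(pathways, "kat_pathways")) {
    graphs <- purrr::map2(pathways$members, pathways$edges, pathway_graph)
    names(graphs) <- pathways$pathway_id
    return(graphs)
  }
  if (is.list(pathways) && all(vapply(pathways, inherits, logical(1L),
                                      "pathway_graph"))) {
    if (is.null(names(pathways)) || any(names(pathways) == "")) {
      stop("pathway list must be named by pathway id")
    }
    return(pathways)
  }
  stop("`pathways` must come from read_pathways() or be a named list of pathway_graph objects")
}
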