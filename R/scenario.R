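KNOWLEDGE_LEVELS <- c("complete", "missing_edges_5", "missing_edges_15",
                      "missing_nodes")
STRUCTURE_LEVELS <- c("perfect", "mismatch_10", "mismatch_40", "mismatch_70",
                      "complete_mismatch", "no_pathway")
METHOD_LEVELS <- c("pairkat", "laplacian", "none", "pc_ftest", "simes")

#' Simulation scenario configuration
#'
#' One cell of the type-I-error / power study: a pathway *knowledge*
#' scenario (what part of the true graph the analyst gets to see) crossed
#' with a pathway *structure* scenario (how corrupted the surviving edges
#' are).  Data are always generated from the true graph; only the graph
#' handed to the test differs.
#'
#' @param p Pathway size (nodes); the study uses 15, 30 or 45.
#' @param n Sample size (default 160).
#' @param reps Monte Carlo replicates (default 1000).
#' @param beta_effect Per-feature outcome coefficient: 0 for the null, 0.1
#'   for the reference alternative.
#' @param tau Laplacian smoothing bandwidth (default 1).
#' @param knowledge One of `"complete"`, `"missing_edges_5"`,
#'   `"missing_edges_15"` (data generated from a densified graph, test given
#'   the sparse one), `"missing_nodes"` (weakly connected nodes randomly
#'   dropped before testing).
#' @param structure One of `"perfect"`, `"mismatch_10"`, `"mismatch_40"`,
#'   `"mismatch_70"` (per-edge rewiring probability), `"complete_mismatch"`
#'   (edge-disjoint replacement graph), `"no_pathway"` (test ignores the
#'   graph).
#' @param alpha Rejection level (default 0.05).
#' @param seed Master seed; per-replicate seeds are derived from it so runs
#'   are reproducible and order-independent.
#' @param bandwidth Kernel bandwidth rule, see [median_bandwidth()].
#' @param sigma Residual standard deviation of the outcome model.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(p = 30, n = 160, reps = 1000, beta_effect = 0,
                       tau = 1, knowledge = "complete",
                       structure = "perfect", alpha = 0.05, seed = 1,
                       bandwidth = "median_dist", sigma = 1.3688) {
  knowledge <- match.arg(knowledge, KNOWLEDGE_LEVELS)
  structure_ <- match.arg(structure, STRUCTURE_LEVELS)
  stopifnot(p >= 4, n > 3, reps >= 1, tau >= 0, alpha > 0, alpha < 1,
            sigma > 0)
  bandwidth <- match.arg(bandwidth, c("median_dist", "median_sqdist"))
  structure(
    list(p = as.integer(p), n = as.integer(n), reps = as.integer(reps),
         beta_effect = beta_effect, tau = tau, knowledge = knowledge,
         structure = structure_, alpha = alpha, seed = as.integer(seed),
         bandwidth = bandwidth, sigma = sigma),
    class = "sim_config")
}

#' Read a scenario configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [sim_config()].
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  # YAML 1.1 turns a bare `n` key into the boolean FALSE; undo that
  names(vals)[names(vals) == "FALSE"] <- "n"
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

# one replicate: returns a named vector of p-values, one per method
simulate_replicate <- function(cfg, methods) {
  g0 <- sample_ba_graph(cfg$p)
  g_gen <- switch(cfg$knowledge,
    complete         = g0,
    missing_edges_5  = densify_graph(g0, 0.05),
    missing_edges_15 = densify_graph(g0, 0.15),
    missing_nodes    = g0)
  omega <- precision_from_adjacency(g_gen)
  z <- sample_features(omega, cfg$n)
  out <- sample_outcome(z, cfg$beta_effect, sigma = cfg$sigma)

  if (cfg$knowledge == "missing_nodes") {
    dr <- drop_low_degree_nodes(g0)
    g_base <- dr$graph
    zs <- z[, dr$kept, drop = FALSE]
  } else {
    g_base <- g0
    zs <- z
  }
  g_test <- switch(cfg$structure,
    perfect           = g_base,
    mismatch_10       = rewire_edges(g_base, 0.10),
    mismatch_40       = rewire_edges(g_base, 0.40),
    mismatch_70       = rewire_edges(g_base, 0.70),
    complete_mismatch = disjoint_edge_graph(g_base),
    no_pathway        = g_base)

  nf <- fit_null(out$y, out$x)
  pv <- vapply(methods, function(m) {
    if (m %in% c("pairkat", "laplacian") && cfg$structure == "no_pathway") {
      m <- "none"
    }
    switch(m,
      pairkat = {
        lr <- regularize_laplacian(normalized_laplacian(g_test), cfg$tau)
        zp <- project_features(zs, lr)
        kernel_test_pvalue(
          nf, gaussian_kernel(zp, median_bandwidth(zp, cfg$bandwidth)))$p_value
      },
      laplacian = {
        zp <- project_features(zs, normalized_laplacian(g_test))
        kernel_test_pvalue(
          nf, gaussian_kernel(zp, median_bandwidth(zp, cfg$bandwidth)))$p_value
      },
      none = kernel_test_pvalue(
        nf, gaussian_kernel(zs, median_bandwidth(zs, cfg$bandwidth)))$p_value,
      pc_ftest = pc_f_test(out$y, out$x, zs),
      simes = univariate_simes(out$y, out$x, zs))
  }, numeric(1L))
  names(pv) <- methods
  pv
}

#' Run one simulation scenario
#'
#' Executes the full per-replicate pipeline -- sample the true graph,
#' derive the precision matrix, draw features and outcome, corrupt the
#' graph per the knowledge and structure scenario, test -- and tallies
#' rejections at `cfg$alpha` for each requested method.
#'
#' @param cfg A [sim_config()].
#' @param methods Character vector from `"pairkat"`, `"laplacian"`,
#'   `"none"`, `"pc_ftest"`, `"simes"`.
#' @return An object of class `kat_sim`; `tidy()` gives one row per method
#'   with `rejection_rate`, `reps_completed` and `mc_se`, and `$pvalues`
#'   holds the full replicate-by-method p-value table.
#' @examples
#' sim <- run_scenario(sim_config(p = 8, n = 40, reps = 5), "pairkat")
#' tidy(sim)
#' @export
run_scenario <- function(cfg, methods = "pairkat") {
  stopifnot(inherits(cfg, "sim_config"))
  methods <- match.arg(methods, METHOD_LEVELS, several.ok = TRUE)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$reps)
  pv <- matrix(NA_real_, cfg$reps, length(methods),
               dimnames = list(NULL, methods))
  failed <- 0L
  for (i in seq_len(cfg$reps)) {
    set.seed(rep_seeds[i])
    res <- tryCatch(simulate_replicate(cfg, methods),
                    error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else pv[i, ] <- res
  }
  done <- colSums(!is.na(pv))
  rate <- colMeans(pv < cfg$alpha, na.rm = TRUE)
  summary <- tibble::tibble(
    method = methods,
    rejection_rate = as.numeric(rate),
    reps_completed = as.integer(done),
    mc_se = sqrt(rate * (1 - rate) / done),
    p = cfg$p, n = cfg$n, beta_effect = cfg$beta_effect, tau = cfg$tau,
    knowledge = cfg$knowledge, structure = cfg$structure,
    alpha = cfg$alpha, seed = cfg$seed)
  structure(list(summary = summary,
                 pvalues = tibble::as_tibble(as.data.frame(pv)),
                 config = cfg, failed = failed),
            class = "kat_sim")
}

#' @export
print.kat_sim <- function(x, ...) {
  cat("<kat_sim> ", x$config$knowledge, " / ", x$config$structure,
      ", p = ", x$config$p, ", beta = ", x$config$beta_effect,
      ", reps = ", x$config$reps,
      if (x$failed) paste0(" (", x$failed, " failed)"), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Power as a function of signal-to-noise ratio
#'
#' Sweeps a global multiplier on the reference effect size (beta = 0.1 per
#' feature), recording for each grid point the mean realized
#' signal-to-noise ratio (averaged over the random graphs) and the
#' empirical power of each method under perfect pathway knowledge.  Graphs
#' and features are shared across the grid within a replicate, so curves
#' are positively coupled and smooth.
#'
#' @param multipliers Effect-size multipliers to sweep.
#' @param cfg Base [sim_config()] (its `beta_effect` is ignored).
#' @param methods Methods to track, see [run_scenario()].
#' @return A tibble of class `kat_power_sweep`: one row per multiplier and
#'   method with `snr` and `power`.
#' @export
power_snr_sweep <- function(multipliers, cfg = sim_config(),
                            methods = c("pairkat", "none")) {
  stopifnot(inherits(cfg, "sim_config"))
  methods <- match.arg(methods, METHOD_LEVELS, several.ok = TRUE)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$reps)
  den <- 0.25 * 0.25 + 0.0625 / 12 + cfg$sigma^2
  nm <- length(multipliers)
  rej <- array(0, c(cfg$reps, nm, length(methods)))
  snr <- matrix(NA_real_, cfg$reps, nm)
  ok <- rep(FALSE, cfg$reps)
  for (i in seq_len(cfg$reps)) {
    set.seed(rep_seeds[i])
    res <- tryCatch({
      g <- sample_ba_graph(cfg$p)
      omega <- precision_from_adjacency(g)
      z <- sample_features(omega, cfg$n)
      lr <- regularize_laplacian(normalized_laplacian(g), cfg$tau)
      ones <- rep(1, cfg$p)
      base_num <- drop(crossprod(ones, solve(omega, ones)))  # 1' Sigma 1
      row_p <- matrix(NA_real_, nm, length(methods))
      row_snr <- numeric(nm)
      for (k in seq_len(nm)) {
        b <- 0.1 * multipliers[k]
        out <- sample_outcome(z, b, sigma = cfg$sigma)
        nf <- fit_null(out$y, out$x)
        row_snr[k] <- b^2 * base_num / den
        for (j in seq_along(methods)) {
          row_p[k, j] <- switch(methods[j],
            pairkat = {
              zp <- project_features(z, lr)
              kernel_test_pvalue(nf, gaussian_kernel(
                zp, median_bandwidth(zp, cfg$bandwidth)))$p_value
            },
            laplacian = {
              zp <- project_features(z, normalized_laplacian(g))
              kernel_test_pvalue(nf, gaussian_kernel(
                zp, median_bandwidth(zp, cfg$bandwidth)))$p_value
            },
            none = kernel_test_pvalue(nf, gaussian_kernel(
              z, median_bandwidth(z, cfg$bandwidth)))$p_value,
            pc_ftest = pc_f_test(out$y, out$x, z),
            simes = univariate_simes(out$y, out$x, z))
        }
      }
      list(p = row_p, snr = row_snr)
    }, error = function(e) NULL)
    if (is.null(res)) next
    ok[i] <- TRUE
    rej[i, , ] <- res$p < cfg$alpha
    snr[i, ] <- res$snr
  }
  grid <- tidyr::expand_grid(multiplier = multipliers, method = methods)
  grid$snr <- rep(colMeans(snr[ok, , drop = FALSE]), each = length(methods))
  grid$power <- as.vector(t(apply(rej[ok, , , drop = FALSE], c(2, 3), mean)))
  grid$reps <- sum(ok)
  class(grid) <- c("kat_power_sweep", class(grid))
  grid
}

#' Interpolated SNR at which a power curve crosses a target
#'
#' Linear interpolation between the first adjacent pair of sweep points
#' (ordered by SNR) that straddles the target power.
#'
#' @param sweep A [power_snr_sweep()] result.
#' @param target Power level to cross (default 0.8).
#' @return A tibble with one row per method: `method`, `snr_at_target`
#'   (`NA` if the curve never reaches the target within the sweep).
#' @export
snr_at_power <- function(sweep, target = 0.8) {
  stopifnot(is.data.frame(sweep), all(c("method", "snr", "power") %in%
                                        names(sweep)))
  dplyr::summarise(
    dplyr::group_by(sweep, .data$method),
    snr_at_target = {
      o <- order(.data$snr)
      sn <- .data$snr[o]; pw <- .data$power[o]
      hit <- which(pw[-1] >= target & pw[-length(pw)] < target)
      if (pw[1] >= target) {
        sn[1]
      } else if (!length(hit)) {
        NA_real_
      } else {
        i <- hit[1L]
        sn[i] + (target - pw[i]) * (sn[i + 1] - sn[i]) / (pw[i + 1] - pw[i])
      }
    },
    .groups = "drop")
}
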