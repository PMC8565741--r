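#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for pathway test results
#'
#' `tidy()` returns the per-pathway result table; `glance()` a one-row
#' summary of the fit.
#'
#' @param x A `kat_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kat_test <- function(x, ...) x$results

#' @rdname tidy.kat_test
#' @export
glance.kat_test <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n = x$n, q = x$q, sigma2 = x$sigma2,
    n_pathways = nrow(x$results), n_skipped = length(x$skipped),
    min_p_value = if (nrow(x$results)) min(x$results$p_value) else NA_real_)
}

#' Tidiers for simulation results
#'
#' `tidy()` returns the per-method rejection summary; `glance()` a one-row
#' echo of the scenario.
#'
#' @param x A `kat_sim` object from [run_scenario()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kat_sim <- function(x, ...) x$summary

#' @rdname tidy.kat_sim
#' @export
glance.kat_sim <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(p = cfg$p, n = cfg$n, reps = cfg$reps,
                 beta_effect = cfg$beta_effect, tau = cfg$tau,
                 knowledge = cfg$knowledge, structure = cfg$structure,
                 alpha = cfg$alpha, failed = x$failed)
}

#' Plot pathway test results
#'
#' Dot plot of -log10 p-values by pathway, with a reference line at the
#' 0.05 level.
#'
#' @param object A `kat_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kat_test <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(
      x = -log10(.data$p_value),
      y = stats::reorder(.data$pathway_id, -.data$p_value))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = paste0("Pathway association (", object$mode, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a simulation rejection summary
#'
#' Bars of rejection rate per method with Monte Carlo error bars and a
#' line at the nominal level.
#'
#' @param object A `kat_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kat_sim <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                   y = .data$rejection_rate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$rejection_rate - 2 * .data$mc_se,
      ymax = .data$rejection_rate + 2 * .data$mc_se), width = 0.2) +
    ggplot2::geom_hline(yintercept = object$config$alpha,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "rejection rate") +
    ggplot2::theme_minimal()
}

#' Plot power against signal-to-noise ratio
#'
#' @param object A [power_snr_sweep()] result.
#' @param target Horizontal reference power level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kat_power_sweep <- function(object, target = 0.8, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$snr, y = .data$power,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed") +
    ggplot2::labs(x = "signal-to-noise ratio", y = "empirical power") +
    ggplot2::theme_minimal()
}
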