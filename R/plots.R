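#' Plot moderation p-value distributions across the simulation grid
#'
#' Boxplots of per-replicate moderation p-values for one term, faceted by
#' outcome, against the grid condition that drives it: the binary trait's
#' on-exposure for `term = "binary"`, the health standard deviation for
#' `term = "health"`. The dashed line marks `alpha`.
#'
#' @param x An `"epm_sim_grid"` result (or its `per_rep` tibble).
#' @param term `"binary"` or `"health"`.
#' @param alpha Significance level drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_grid_pvalues <- function(x, term = c("binary", "health"), alpha = 0.05) {
  term <- match.arg(term)
  per_rep <- if (inherits(x, "epm_sim_grid")) x$per_rep else x
  cond <- if (term == "binary") "binary_q" else "health_sd"
  d <- dplyr::filter(per_rep, .data$term == !!term, !is.na(.data$p.value))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data[[cond]]), y = .data$p.value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome)) +
    ggplot2::labs(x = cond, y = paste0(term, "-term p-value"))
}

#' @rdname plot_grid_pvalues
#' @param object An `"epm_sim_grid"` result.
#' @param ... Passed to [plot_grid_pvalues()].
#' @method autoplot epm_sim_grid
#' @export
autoplot.epm_sim_grid <- function(object, ...) {
  plot_grid_pvalues(object, ...)
}

#' Plot held-out cluster performance
#'
#' Scatter of cross-validated pacemaker versus elastic-net MAE (years) for
#' each evaluated residual cluster; the dashed lines mark the merge cutoff.
#'
#' @param reports Tibble from [evaluate_clusters()].
#' @param mae_cutoff Merge cutoff in years.
#' @return A ggplot object.
#' @export
plot_cluster_reports <- function(reports, mae_cutoff = 6) {
  ggplot2::ggplot(reports,
                  ggplot2::aes(x = .data$epm_cv_mae, y = .data$enet_cv_mae,
                               size = .data$n_sites)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = mae_cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = mae_cutoff, linetype = "dashed") +
    ggplot2::labs(x = "EPM cross-validated MAE (years)",
                  y = "Elastic-net cross-validated MAE (years)",
                  size = "Sites")
}
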