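# ggplot2 helpers for the package's result types.

#' Plot the per-column IC profile of a motif
#'
#' @param m A [motif].
#' @return A ggplot: column IC (bits) by position.
#' @export
plot_positional_ic <- function(m) {
  prof <- positional_ic(m)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(limits = c(0, 2)) +
    ggplot2::labs(x = "position", y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.motif_sample <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::labs(x = "sampled IC (bits)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot an IC recovery grid
#'
#' Deviation of the per-cell mean sampled IC from its target, by site
#' count, faceted by target IC, one line per sampler.
#'
#' @param grid Output of [ic_recovery_grid()].
#' @return A ggplot.
#' @export
plot_ic_recovery <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$N, y = .data$mean_dev,
                                     colour = .data$algorithm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_dev - 2 * .data$mc_se,
      ymax = .data$mean_dev + 2 * .data$mc_se)) +
    ggplot2::facet_wrap(~target_ic, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sites per motif (N)",
                  y = "mean sampled IC - target (bits)") +
    ggplot2::theme_minimal()
}

#' Plot IGC against IC for the two samplers
#'
#' @param comparison Output of [igc_ic_comparison()].
#' @return A ggplot of mean IGC by target IC per sampler.
#' @export
plot_igc_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(
    comparison, cols = c("mean_igc_maxent", "mean_igc_tu"),
    names_to = "algorithm", values_to = "mean_igc",
    names_prefix = "mean_igc_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target_ic, y = .data$mean_igc,
                                     colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "target IC (bits)", y = "mean IGC") +
    ggplot2::theme_minimal()
}

#' Plot IC p-value tail curves
#'
#' Bound, moment-matching and importance-sampling estimates on the log10
#' scale across an IC grid.
#'
#' @param curve Output of [ic_pvalue_curve()].
#' @return A ggplot.
#' @export
plot_pvalue_curve <- function(curve) {
  long <- tidyr::pivot_longer(
    curve, cols = c("log10_bound", "log10_moment", "log10_is"),
    names_to = "estimator", values_to = "log10_p", names_prefix = "log10_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ic, y = .data$log10_p,
                                     colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "IC threshold (bits)", y = "log10 p-value") +
    ggplot2::theme_minimal()
}
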