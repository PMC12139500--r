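#' Plot a robustness sweep
#'
#' Mean validation AUC (line and points) with a mean +/- SD ribbon against
#' the fraction of lipid species retained, one colour per method, faceted
#' by validation cohort.
#'
#' @param object A `sweep_result` from [robustness_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  s <- sweep_summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$fraction, y = .data$mean_auc,
                                  colour = .data$method, fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$sd_auc,
                                      ymax = .data$mean_auc + .data$sd_auc),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cohort)) +
    ggplot2::scale_x_reverse(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "lipid species retained", y = "validation AUC",
                  colour = "method", fill = "method") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of an association scan
#'
#' Effect estimate against -log10(q), coloured by the three-tier
#' significance class used throughout the package.
#'
#' @param scan An association table with `beta`, `p`, `q` columns
#'   ([cvd_assoc_scan()] output, or one `term` of [statin_effect_scan()]).
#' @param alpha Significance level for the tiers.
#' @return A ggplot object.
#' @export
plot_assoc_volcano <- function(scan, alpha = 0.05) {
  d <- dplyr::filter(as_tibble(scan), !is.na(.data$p))
  d$class <- ifelse(d$q < alpha, "corrected p < 0.05",
                    ifelse(d$p < alpha, "p < 0.05", "p ≥ 0.05"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = -log10(pmax(.data$q, 1e-300)),
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "effect estimate", y = expression(-log[10](q)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of adjusted vs unadjusted association estimates
#'
#' Draws each lipid's effect in the statin-adjusted model against the
#' unadjusted model, with the line of identity; attenuation pulls points
#' toward the horizontal axis.
#'
#' @param unadjusted,adjusted [cvd_assoc_scan()] outputs over the same
#'   lipids.
#' @return A ggplot object.
#' @export
plot_adjustment_scatter <- function(unadjusted, adjusted) {
  d <- dplyr::inner_join(
    dplyr::select(as_tibble(unadjusted), "lipid", beta_unadjusted = "beta"),
    dplyr::select(as_tibble(adjusted), "lipid", beta_adjusted = "beta"),
    by = "lipid")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_unadjusted,
                                  y = .data$beta_adjusted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = "log OR, no statin adjustment",
                  y = "log OR, statin adjusted") +
    ggplot2::theme_minimal()
}
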