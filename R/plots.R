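#' Volcano-style plot of spatial differential expression
#'
#' Bayes factor (log10) against log2 fold change, faceted by AAR, with the
#' call thresholds drawn.
#'
#' @param de A [run_de()] tibble.
#' @param bf_threshold,lfc_threshold Thresholds to draw (defaults 3 and 1).
#' @return A ggplot object.
#' @export
plot_de <- function(de, bf_threshold = 3, lfc_threshold = 1) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc, y = log10(.data$bf),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = log10(bf_threshold),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~aar) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "log10 Bayes factor",
                  colour = "called") +
    ggplot2::theme_minimal()
}

#' Heatmap of neighborhood decile enrichment
#'
#' @param object An `enrichment_matrix`.
#' @param ... Unused.
#' @return A ggplot object (blue-white-red z-score tile map).
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  z <- object$z
  df <- tidyr::expand_grid(d1 = seq_len(nrow(z)), d2 = seq_len(ncol(z))) |>
    mutate(z = as.vector(z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d1, y = .data$d2,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey80") +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(z))) +
    ggplot2::scale_y_continuous(breaks = seq_len(ncol(z))) +
    ggplot2::labs(x = "decile", y = "decile", fill = "z") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Module batch scores by layer and age group
#'
#' @param batch_scores Per-(array, AAR) scores from [score_modules()].
#' @param modules Optional subset of module ids to show.
#' @return A ggplot object.
#' @export
plot_module_scores <- function(batch_scores, modules = NULL) {
  d <- batch_scores
  if (!is.null(modules)) d <- d |> filter(.data$module %in% modules)
  d <- d |> mutate(
    aar = factor(.data$aar, levels = aar_levels()),
    age_group = factor(.data$age_group, levels = age_groups())
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$aar, y = .data$score,
                                  fill = .data$age_group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~module, scales = "free_y") +
    ggplot2::labs(x = "anatomical region", y = "module score",
                  fill = "age group") +
    ggplot2::theme_minimal()
}

#' Power curves from the simulation power study
#'
#' @param power A `power_result` (rows from one or more
#'   [estimate_power()] runs bound together).
#' @param aar Which stratum to draw (default `"overall"`).
#' @return A ggplot object of power vs fold change with CIs.
#' @export
plot_power_curve <- function(power, aar = "overall") {
  d <- power |> filter(.data$aar == !!aar)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fold_change, y = .data$power,
                                  colour = .data$level,
                                  group = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = "fold change", y = "power (BF > 3)",
                  colour = "expression level") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
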