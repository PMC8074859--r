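#' Box-and-jitter plots of diversity metrics by group
#'
#' One facet per metric, groups on the x axis -- the layout used for
#' whisker-plot comparisons of Shannon entropy, Gini coefficients and
#' HEC statistics between cohort arms.
#'
#' @param summaries Diversity summary tibble (see
#'   [summarize_repertoire()]).
#' @param metrics Metric columns to show.
#' @return A ggplot object.
#' @export
plot_diversity <- function(summaries,
                           metrics = c("entropy", "gini_clone",
                                       "hec_count", "hec_cum_freq")) {
  long <- tidyr::pivot_longer(summaries,
                              cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Stacked V or J segment usage bars per sample
#'
#' @param clonotypes Combined clonotype tibble with `sample_id`.
#' @param segment `"v_call"` or `"j_call"`.
#' @return A ggplot object (per-sample stacked read-frequency bars).
#' @export
plot_segment_usage <- function(clonotypes, segment = c("v_call",
                                                       "j_call")) {
  segment <- match.arg(segment)
  usage <- clonotypes |>
    dplyr::count(.data$sample_id, .data[[segment]], wt = .data$count,
                 name = "reads") |>
    dplyr::mutate(frequency = .data$reads / sum(.data$reads),
                  .by = "sample_id")
  ggplot2::ggplot(usage, ggplot2::aes(x = .data$sample_id,
                                      y = .data$frequency,
                                      fill = .data[[segment]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "frequency of reads") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   legend.position = "none")
}

#' @method autoplot repdiv_correlation
#' @export
autoplot.repdiv_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = object$conf_band,
      ggplot2::aes(x = .data$x, ymin = .data$lwr, ymax = .data$upr),
      inherit.aes = FALSE, fill = "grey80") +
    ggplot2::geom_line(
      data = object$conf_band,
      ggplot2::aes(x = .data$x, y = .data$fit), inherit.aes = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Shannon entropy (nats)", y = "expression",
      title = object$label,
      subtitle = sprintf("cor = %.3f, p = %.3g", object$r,
                         object$p_value)) +
    ggplot2::theme_bw()
}
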