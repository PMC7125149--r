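# ggplot2 views of the main result types: a volcano plot per contrast, state
# counts, per-condition fraction mean differences, and the enrichment
# heatmap (-log10 p fill with overlap counts, one cell per set pair).

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.polystate_contrast <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#1b9e77", down = "#d95f02", none = "grey60")) +
    ggplot2::labs(
      x = "log2 fold change (B vs A)", y = "-log10 p",
      title = paste0("Stage contrast, ", attr(object, "fraction"),
                     " fraction"),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of isoform counts per regulation state
#'
#' @param summary A `polystate_state_summary` row from [summarize_states()].
#' @return A ggplot object.
#' @export
plot_state_summary <- function(summary) {
  counts <- tidyr::pivot_longer(
    as_tibble(summary)[.states],
    dplyr::everything(),
    names_to = "state", values_to = "count")
  counts$state <- factor(counts$state, levels = .states)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$state, y = .data$count)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::labs(x = NULL, y = "isoforms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Mean fraction differences per condition
#'
#' Plots per-replicate closed fraction differences (points) and condition
#' means (bars) for one minuend - subtrahend pair.
#'
#' @inheritParams fraction_difference
#' @return A ggplot object.
#' @export
plot_fraction_difference <- function(profiles, minuend = "HP",
                                     subtrahend = "F") {
  diffs <- fraction_difference(profiles, minuend, subtrahend)
  ggplot2::ggplot(diffs$means,
                  ggplot2::aes(x = .data$condition,
                               y = .data$mean_difference)) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_jitter(data = diffs$replicates,
                         ggplot2::aes(y = .data$difference),
                         width = 0.08, size = 2) +
    ggplot2::labs(x = NULL,
                  y = paste0(minuend, " - ", subtrahend,
                             " (closed fractions)")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.polystate_enrichment <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$target_set, y = .data$input_set,
                               fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$overlap), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 p") +
    ggplot2::theme_minimal()
}
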