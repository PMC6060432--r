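#' Plot a group trace summary
#'
#' Mean relative ratio over time with a +/- SEM ribbon, one colour per
#' genotype when a `genotype` column is present.
#'
#' @param object A [group_summary()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_trace_summary <- function(object, ...) {
  has_geno <- "genotype" %in% names(object)
  mapping <- if (has_geno) {
    ggplot2::aes(
      x = .data$time_min, y = .data$mean,
      colour = .data$genotype, fill = .data$genotype
    )
  } else {
    ggplot2::aes(x = .data$time_min, y = .data$mean)
  }
  ggplot2::ggplot(object, mapping) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (min)", y = "Relative YFP/CFP ratio (%)",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cell relative traces
#'
#' @param traces A relative-trace tibble (`cell_id`, `time_min`, `value`).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces) {
  ggplot2::ggplot(
    traces,
    ggplot2::aes(x = .data$time_min, y = .data$value, group = .data$cell_id)
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Time (min)", y = "Relative YFP/CFP ratio (%)") +
    ggplot2::theme_minimal()
}

#' Plot detection occurrences by genotype
#'
#' Side-by-side bars of integer percent occurrence per feature, from a
#' [compare_genotypes()] table.
#'
#' @param comparison A [compare_genotypes()] result.
#' @return A ggplot object.
#' @export
plot_occurrence <- function(comparison) {
  long <- tidyr::pivot_longer(
    comparison[, c("feature", "pct_nonTg", "pct_3xTgAD")],
    cols = c("pct_nonTg", "pct_3xTgAD"),
    names_to = "genotype", values_to = "percent",
    names_prefix = "pct_"
  )
  long$feature <- factor(long$feature, levels = comparison$feature)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$feature, y = .data$percent, fill = .data$genotype)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Occurrence (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
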