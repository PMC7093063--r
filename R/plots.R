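#' Trough-category distribution plot
#'
#' Grouped bar chart of the proportion of troughs in each category
#' (subtherapeutic / therapeutic / supratherapeutic) per cohort -- the
#' standard way to display target-attainment results.
#'
#' @param data A data frame with `group` and `trough_mcg_ml` columns.
#'
#' @return A ggplot object.
#' @examples
#' troughs <- tibble::tibble(
#'   group = rep(c("control", "intervention"), each = 20),
#'   trough_mcg_ml = c(runif(20, 4, 22), runif(20, 9, 21))
#' )
#' plot_trough_distribution(troughs)
#' @export
plot_trough_distribution <- function(data) {
  summary <- summarize_cohort(data)
  long <- tidyr::pivot_longer(
    summary,
    dplyr::starts_with("prop_"),
    names_to = "category", names_prefix = "prop_", values_to = "proportion"
  )
  long$category <- factor(long$category, levels = TROUGH_LEVELS)
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$category, y = .data$proportion, fill = .data$group
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = NULL, y = "Proportion of first troughs", fill = NULL,
      title = "Initial vancomycin trough distribution",
      subtitle = "Therapeutic window 10–20 mcg/ml"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trough_distribution
#' @param object A `trough_comparison` from [compare_cohorts()].
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.trough_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary,
    dplyr::starts_with("prop_"),
    names_to = "category", names_prefix = "prop_", values_to = "proportion"
  )
  long$category <- factor(long$category, levels = TROUGH_LEVELS)
  long$group <- factor(long$group, levels = object$groups)
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$category, y = .data$proportion, fill = .data$group
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.0f%%", 100 * .data$proportion)),
      position = ggplot2::position_dodge(width = 0.8),
      vjust = -0.4, size = 3
    ) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = NULL, y = "Proportion of first troughs", fill = NULL,
      title = "Initial vancomycin trough distribution by cohort"
    ) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
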