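measure_labels <- c(
  p_subject_prediction = "P(predict subject referent)",
  p_pronoun_given_predicted_subject = "P(predict pronoun | predicted subject)",
  p_pronoun_given_predicted_object = "P(predict pronoun | predicted object)"
)

category_palette <- c(
  subject_biased = "#1b9e77", neutral = "#d95f02", object_biased = "#7570b3"
)

#' Plot binned learning curves
#'
#' One panel per measure; one line per group (verb category or verb), with
#' the grand-average proportion against the bin index.
#'
#' @param object A `refbias_curves` tibble from [bin_proportions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.refbias_curves <- function(object, ...) {
  df <- dplyr::filter(object, !.data$empty)
  df$measure <- factor(
    measure_labels[df$measure],
    levels = unname(measure_labels[unique(object$measure)])
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin_index, y = .data$proportion, colour = .data$group
  )) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "input items presented (bins of 100)",
      y = "grand-average proportion",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (all(unique(df$group) %in% names(category_palette))) {
    p <- p + ggplot2::scale_colour_manual(values = category_palette)
  }
  p
}

#' Plot novel-item predictions
#'
#' Bar chart of the pooled frozen-learning predictions by novelty
#' condition, one panel per measure.
#'
#' @param object A `refbias_novel` tibble from [novel_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.refbias_novel <- function(object, ...) {
  df <- object
  df$measure <- factor(
    measure_labels[df$measure],
    levels = unname(measure_labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$condition, y = .data$proportion, fill = .data$condition
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey40") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "pooled proportion") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
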