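# Figure-style plots: per-set distribution panels with significance stars,
# a p-value matrix for comparison tables, and annotation-tally bars.

#' Per-set distribution boxplots with significance stars
#'
#' Draws one box per gene set (optionally faceted, e.g. by cohort) and
#' places a star above each set that is the significantly higher member of
#' at least one pairwise comparison.
#'
#' @param data Long data frame.
#' @param value,set Tidy-eval columns holding values and set labels.
#' @param comparisons Optional `dg_comparisons` object from
#'   [compare_sets()] used to place the stars.
#' @param facet Optional tidy-eval faceting column.
#' @return A `ggplot` object.
#' @export
plot_set_distributions <- function(data, value, set, comparisons = NULL,
                                   facet = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = {{ set }}, y = {{ value }},
                                          fill = {{ set }})) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
  if (!rlang::quo_is_null(rlang::enquo(facet))) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars({{ facet }}),
                                 scales = "free_y")
  }
  if (!is.null(comparisons)) {
    starred <- unique(stats::na.omit(comparisons$higher))
    if (length(starred) > 0L) {
      vals <- dplyr::pull(data, {{ value }})
      sets <- as.character(dplyr::pull(data, {{ set }}))
      ypos <- vapply(starred, function(s) {
        max(vals[sets == s]) * 1.05
      }, numeric(1))
      p <- p + ggplot2::annotate("text", x = starred, y = ypos,
                                 label = "*", size = 6)
    }
  }
  p
}

#' Plot a pairwise-comparison table as a significance matrix
#'
#' @param object A `dg_comparisons` object.
#' @param ... Unused.
#' @return A `ggplot` tile plot of -log10 p-values, starred where
#'   significant.
#' @method autoplot dg_comparisons
#' @export
autoplot.dg_comparisons <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(label = ifelse(.data$significant,
                          sprintf("%.3g *", .data$p_value),
                          sprintf("%.3g", .data$p_value)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_a, y = .data$set_b,
                                   fill = -log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = expression(-log[10] * "p")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s pairwise set comparisons",
                                  df$test[[1L]])) +
    ggplot2::theme_minimal()
}

#' Bar chart of annotation-tally percentages
#'
#' @param per_label The `per_label` tibble from [tally_associations()].
#' @param top_n Show the `top_n` largest categories; default 10.
#' @return A `ggplot` object; percentages printed to one decimal place.
#' @export
plot_annotation_tally <- function(per_label, top_n = 10) {
  df <- head(per_label, top_n) %>%
    mutate(label = factor(.data$label, levels = rev(.data$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percentage, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%",
                                                    .data$percentage)),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "% of association pairs", y = NULL) +
    ggplot2::theme_minimal()
}

#' Degree distributions by gene set
#'
#' @param metrics Tibble from [node_metrics()] on a labelled network.
#' @return A `ggplot` object (log1p-scaled degree boxplots per set).
#' @export
plot_degree_by_set <- function(metrics) {
  stopifnot("set_label" %in% names(metrics))
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$set_label,
                                        y = .data$degree + 1,
                                        fill = .data$set_label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "degree + 1") +
    ggplot2::theme_minimal()
}
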