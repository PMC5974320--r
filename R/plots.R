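# ggplot2 helpers for the standard result shapes.

#' Plot mean fraction profiles along the axis, per category
#'
#' @param fractions long tibble (`gene_id`, `segment`, `fraction`; consensus
#'   profiles from [consensus_fractions()] work directly).
#' @param categories optional tibble with `gene_id`, `category` to colour by.
#' @return a ggplot object: segment (animal to vegetal) on x, mean fraction
#'   with per-gene traces on y.
#' @export
plot_profiles <- function(fractions, categories = NULL) {
  df <- fractions
  if (!is.null(categories)) {
    df <- inner_join(df, select(categories, "gene_id", "category"), by = "gene_id")
  } else {
    df$category <- "all"
  }
  segs <- segment_levels(df)
  df <- mutate(df, segment = factor(.data$segment, levels = segs))
  mean_df <- df |>
    group_by(.data$category, .data$segment) |>
    summarise(fraction = mean(.data$fraction), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$fraction,
                                   group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.08, colour = "grey40") +
    ggplot2::geom_line(data = mean_df,
                       ggplot2::aes(group = .data$category, colour = .data$category),
                       linewidth = 1.1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$category)) +
    ggplot2::labs(x = "segment (animal → vegetal)", y = "fraction of signal",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Heatmap of motif presence proportions per category
#'
#' @param presence tibble from [presence_summary()].
#' @return ggplot tile plot, motifs by categories, fill = proportion of
#'   UTRs with at least one occurrence.
#' @export
plot_presence_heatmap <- function(presence) {
  ggplot2::ggplot(presence,
                  ggplot2::aes(x = .data$category, y = .data$motif_id,
                               fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", 100 * .data$proportion)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "UTRs with motif") +
    ggplot2::theme_minimal()
}

#' Bar chart of localization category proportions
#'
#' @param summary tibble from [summarize_categories()].
#' @return ggplot bar chart.
#' @export
plot_category_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$category, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "proportion of molecules") +
    ggplot2::theme_minimal()
}
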