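#' Violin-style comparison of tool scores by class
#'
#' Plots class-conditional score distributions (benign left, pathogenic
#' right) for each prediction tool, the visual counterpart of
#' [evaluate_tool_separation()].
#'
#' @param labeled_scores Tibble with `significance` plus tool columns.
#' @return A ggplot object.
#' @export
plot_tool_separation <- function(labeled_scores) {
  tools <- intersect(.cr_tools, names(labeled_scores))
  long <- labeled_scores |>
    dplyr::mutate(label = dplyr::case_when(
      .data$significance %in% c("P", "LP") ~ "pathogenic",
      .data$significance %in% c("B", "LB") ~ "benign",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$label)) |>
    tidyr::pivot_longer(dplyr::all_of(tools), names_to = "tool",
                        values_to = "score") |>
    dplyr::filter(!is.na(.data$score))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$score,
                                     fill = .data$label)) +
    ggplot2::geom_violin(trim = TRUE, show.legend = FALSE) +
    ggplot2::stat_summary(fun = median, geom = "point", size = 1,
                          show.legend = FALSE) +
    ggplot2::facet_wrap(~tool, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "deleteriousness score") +
    ggplot2::theme_minimal()
}

#' Top-ranked genes per population
#'
#' Horizontal bars of the highest gene carrier rates within each population.
#'
#' @param table A `carrier_table`.
#' @param top_k Genes per population (default 10).
#' @return A ggplot object.
#' @export
plot_top_genes <- function(table, top_k = 10) {
  top <- table |>
    dplyr::group_by(.data$population) |>
    dplyr::slice_min(.data$rank, n = top_k) |>
    dplyr::ungroup()
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$gcr,
    y = stats::reorder(interaction(.data$gene, .data$population),
                       -.data$rank))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~population, scales = "free_y") +
    ggplot2::scale_y_discrete(labels = \(l) sub("\\..*$", "", l)) +
    ggplot2::labs(x = "gene carrier rate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cohort correlation heatmap
#'
#' Tile map of pairwise cohort correlations, optionally row-wise Z-scaled
#' (each row centred and scaled so the best-matching counterpart stands out).
#'
#' @param cor_tbl Output of [correlation_matrix()].
#' @param coefficient Column to plot (default `"spearman_r"`).
#' @param z_scale Row-wise Z-scale the coefficients first.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(cor_tbl, coefficient = "spearman_r",
                                     z_scale = FALSE) {
  if (z_scale) {
    dat <- cor_row_zscale(cor_tbl, coefficient)
    fill_col <- "z"
  } else {
    dat <- cor_tbl
    fill_col <- coefficient
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cohort_b, y = .data$cohort_a,
                                    fill = .data[[fill_col]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[fill_col]])), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  midpoint = if (z_scale) 0 else 0.5) +
    ggplot2::labs(x = NULL, y = NULL, fill = fill_col) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.carrier_table <- function(object, top_k = 10, ...) {
  plot_top_genes(object, top_k = top_k)
}

#' @export
autoplot.cr_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = rank(.data$gcr_a), y = rank(.data$gcr_b))) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = paste("rank of carrier rate,", object$cohort_a),
      y = paste("rank of carrier rate,", object$cohort_b),
      subtitle = sprintf("Spearman R = %.2f, Pearson R = %.2f",
                         object$spearman_r, object$pearson_r)) +
    ggplot2::theme_minimal()
}
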