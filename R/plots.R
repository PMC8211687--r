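#' Dot plot of a checkpoint interaction panel
#'
#' One dot per (axis, sender, receiver): size encodes the permutation
#' significance (`-log10` of the empirical P, floored at one permutation
#' unit), color the interaction score.
#'
#' @param object A `checkpoint_result` from [checkpoint_panel()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot checkpoint_result
#' @export
autoplot.checkpoint_result <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(
      direction = paste(.data$sender, "→", .data$receiver),
      neg_log_p = -log10(pmax(.data$p, 1 / (.data$n_perm + 1)))
    ) |>
    filter(!is.na(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$direction)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$neg_log_p,
                                     color = .data$score)) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "checkpoint axis", y = NULL,
                  size = expression(-log[10] ~ "empirical P"),
                  color = "interaction score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Volcano-style overview of an interactome result
#'
#' Median per-pair interaction score against `-log10` Storey q, with the
#' significance thresholds drawn as dashed lines.
#'
#' @param object An `interactome_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot interactome_result
#' @export
autoplot.interactome_result <- function(object, ...) {
  df <- object$summary |>
    mutate(neg_log_q = -log10(pmax(.data$storey_q, .Machine$double.xmin)))
  ggplot2::ggplot(df, ggplot2::aes(.data$median_score, .data$neg_log_q,
                                   color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$params$score_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$params$q_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "median interaction score",
                  y = expression(-log[10] ~ q), color = "significant") +
    ggplot2::theme_minimal()
}

#' Heatmap of a CNV profile
#'
#' Cells by genomic windows, colored by the smoothed reference-centered
#' relative expression; windows are ordered along the genome. For large
#' matrices only the first `max_cells` cells are drawn.
#'
#' @param object A `cnv_profile`.
#' @param max_cells Cap on the number of cells drawn (default 200).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cnv_profile
#' @export
autoplot.cnv_profile <- function(object, max_cells = 200L, ...) {
  sc <- object$scores
  if (nrow(sc) > max_cells) sc <- sc[seq_len(max_cells), , drop = FALSE]
  df <- as_tibble(sc, rownames = "barcode") |>
    tidyr::pivot_longer(-"barcode", names_to = "window",
                        values_to = "score") |>
    mutate(window = as.integer(sub("^w", "", .data$window)))
  ggplot2::ggplot(df, ggplot2::aes(.data$window, .data$barcode,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "genomic window", y = NULL, fill = "CNV score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Scatter plot of two cell-type proportions across samples
#'
#' @param comp A [composition()] tibble.
#' @param type_a,type_b Cell types on the x and y axes.
#' @return A ggplot with a least-squares trend line.
#' @export
plot_proportions <- function(comp, type_a, type_b) {
  wide <- comp |>
    filter(.data$cell_type %in% c(type_a, type_b)) |>
    select("sample", "cell_type", "proportion") |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "proportion")
  ggplot2::ggplot(wide, ggplot2::aes(.data[[type_a]], .data[[type_b]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey40") +
    ggplot2::labs(x = paste("proportion", type_a),
                  y = paste("proportion", type_b)) +
    ggplot2::theme_minimal()
}
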