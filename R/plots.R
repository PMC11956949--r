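# ggplot2 visualisations for the main result types.

#' Volcano plot of a differential search result
#'
#' Plots `-log10(p)` against `log2fc`, coloured by volcano category, with
#' the fold-change and significance threshold guides.
#'
#' @param object A `newsecm_search` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.newsecm_search <- function(object, ...) {
  tbl <- object$table
  fc_thr <- object$params$fc_threshold
  ggplot2::ggplot(
    tbl,
    ggplot2::aes(
      x = .data$log2fc, y = -log10(.data$p), colour = .data$category
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_vline(
      xintercept = c(-fc_thr, fc_thr), linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::scale_colour_manual(values = stats::setNames(
      c("#c0392b", "#2980b9", "grey70"),
      c(
        paste0("high_in_", object$params$group_a),
        paste0("high_in_", object$params$group_b), "NS"
      )
    )) +
    ggplot2::labs(
      x = expression(log[2] ~ "fold change (geometric means)"),
      y = expression(-log[10] ~ italic(p)),
      colour = NULL,
      title = sprintf(
        "%s vs %s", object$params$group_a, object$params$group_b
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of matrisome category counts or intensities
#'
#' @param summary Tibble from [category_summary()].
#' @param what `"counts"` or `"intensity"`.
#' @return A ggplot object.
#' @export
plot_category_summary <- function(summary, what = c("counts", "intensity")) {
  what <- match.arg(what)
  long <- summary |>
    dplyr::filter(.data$category != "non-matrisome") |>
    tidyr::pivot_longer(
      cols = if (what == "counts") {
        c("n_input", "n_eluate")
      } else {
        c("intensity_input", "intensity_eluate")
      },
      names_to = "fraction", values_to = "value"
    ) |>
    dplyr::mutate(
      fraction = ifelse(grepl("input", .data$fraction), "input", "eluate")
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$category, y = .data$value, fill = .data$fraction)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL,
      y = if (what == "counts") "protein groups" else "summed intensity",
      fill = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Display a DAPI map over its source image
#'
#' @param map A `dapi_map`.
#' @param ... Unused.
#' @return A ggplot object showing the binary mask.
#' @export
autoplot.dapi_map <- function(map, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(map$mask)), col = seq_len(ncol(map$mask))
  )
  df$inside <- as.vector(map$mask)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$inside)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c("FALSE" = "black", "TRUE" = "white")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "tissue") +
    ggplot2::theme_void()
}
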