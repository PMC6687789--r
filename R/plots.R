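#' Plot a C-Index scan
#'
#' Line-and-point plot of the C-Index against the number of clusters, with
#' the selection threshold drawn as a dashed line.
#'
#' @param object A [c_index_scan()] tibble.
#' @param threshold Cut-off to draw; default 0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vm_cindex_scan
#' @export
autoplot.vm_cindex_scan <- function(object, threshold = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$c_index)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters", y = "C-Index") +
    ggplot2::theme_minimal()
}

#' Plot the aggregate curves of a clustering fit
#'
#' Mean Nm/kg curve of each shape/magnitude class over the stance window,
#' one panel per shape, coloured by magnitude.
#'
#' @param object A [cluster_moments()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vm_clustering
#' @export
autoplot.vm_clustering <- function(object, ...) {
  labels <- object$labels
  grid <- object$grid
  long <- purrr::map_dfr(seq_len(nrow(labels)), function(i) {
    tibble(
      shape = labels$shape[i],
      magnitude = labels$magnitude[i],
      stance = grid,
      value = object$curves$curve[[i]]
    )
  })
  agg <- long |>
    dplyr::group_by(.data$shape, .data$magnitude, .data$stance) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$stance, y = .data$value,
                                    colour = .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$shape), scales = "free_y") +
    ggplot2::labs(x = "stance fraction", y = "moment (Nm/kg)",
                  colour = "magnitude") +
    ggplot2::theme_minimal()
}

#' Plot chi-square contributions as a heat map
#'
#' Tile map of per-cell contributions with the observed counts printed in
#' each cell; localises which group/category combinations drive the
#' statistic.
#'
#' @param object A [chi_square_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vm_chisq
#' @export
autoplot.vm_chisq <- function(object, ...) {
  cells <- tidy(object)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$contribution)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$observed), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "(O-E)²/E") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
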