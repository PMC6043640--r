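# ggplot2 views of the result objects. Plots are a convenience surface;
# they reuse tidy() output, so anything shown can also be computed directly.

category_palette <- c(
  time_limit = "grey45", anthropometric = "#3B6FB6", aerobic_power = "#C0392B",
  aerobic_capacity = "#E67E22", anaerobic_capacity = "#27AE60",
  biomechanics = "#8E44AD"
)

circle_layout <- function(nodes) {
  n <- length(nodes)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  tibble(node = nodes, x = cos(theta), y = sin(theta))
}

#' @method autoplot influence_network
#' @export
autoplot.influence_network <- function(object, ...) {
  lay <- circle_layout(object$nodes$name)
  nodes <- dplyr::left_join(lay,
                            dplyr::select(object$nodes, node = "name", "category"),
                            by = "node")
  edges <- object$links |>
    dplyr::left_join(dplyr::rename(lay, xa = "x", ya = "y"),
                     by = c(a = "node")) |>
    dplyr::left_join(dplyr::rename(lay, xb = "x", yb = "y"),
                     by = c(b = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   linewidth = .data$weight, alpha = .data$weight),
      color = "grey30"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$category), size = 4
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y, label = .data$node),
      size = 2.8
    ) +
    ggplot2::scale_color_manual(values = category_palette) +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), guide = "none") +
    ggplot2::scale_alpha(range = c(0.25, 0.9), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "category")
}

#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$node, .data$value), y = .data$value,
      fill = .data$category
    )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::scale_fill_manual(values = category_palette) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @method autoplot node_ranking
#' @export
autoplot.node_ranking <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$node, .data$composite_score),
      y = .data$composite_score, fill = .data$category
    )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = category_palette) +
    ggplot2::labs(x = NULL, y = "composite Borda score") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot an influence-state trajectory
#'
#' Per-node state against step index, log-scaled when all states are
#' positive, annotated with the asymptotic regime.
#'
#' @param traj Output of [influence_trajectory()].
#' @return A ggplot object.
#' @export
plot_influence_trajectory <- function(traj) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$t, y = .data$state, color = .data$node
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      subtitle = sprintf("leading eigenvalue %.4g: %s",
                         attr(traj, "lambda"), attr(traj, "regime")),
      x = "step", y = "state"
    ) +
    ggplot2::theme_minimal(base_size = 10)
  if (all(traj$state > 0)) p <- p + ggplot2::scale_y_log10()
  p
}
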