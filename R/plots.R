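#' Plot a group's activity budgets
#'
#' Stacked per-individual bars of the proportion of sampling points in each
#' behavioral category.
#'
#' @param budgets Tibble from [group_budgets()].
#' @return A ggplot object.
#' @export
plot_activity_budgets <- function(budgets) {
  long <- budgets |>
    dplyr::filter(.data$sampled) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(BEHAVIOR_CATEGORIES),
      names_to = "category", values_to = "proportion"
    ) |>
    dplyr::mutate(category = factor(.data$category, levels = BEHAVIOR_CATEGORIES))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$focal_id, y = .data$proportion, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "Time budget", fill = "Category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a filtered proximity network
#'
#' Circular node layout with edge width proportional to the proximity
#' index; isolates are drawn unconnected.
#'
#' @param object A `filtered_network`.
#' @param centrality Optional `centrality_result` used to size the nodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot filtered_network
#' @export
autoplot.filtered_network <- function(object, centrality = NULL, ...) {
  nodes <- tibble(
    id = object$nodes,
    angle = 2 * pi * (seq_along(object$nodes) - 1) / length(object$nodes)
  ) |>
    dplyr::mutate(x = cos(.data$angle), y = sin(.data$angle))
  if (!is.null(centrality)) {
    nodes <- dplyr::left_join(nodes, as_tibble(centrality), by = "id")
  } else {
    nodes$centrality <- 1
  }
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "id", xf = "x", yf = "y"), by = c(from = "id")) |>
    dplyr::left_join(dplyr::select(nodes, "id", xt = "x", yt = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$xf, y = .data$yf, xend = .data$xt, yend = .data$yt,
        linewidth = .data$weight
      ),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$centrality),
      shape = 15
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y, label = .data$id),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(
      linewidth = "PI", size = "Centrality",
      title = paste0("Filtered proximity network (threshold ",
        format(object$threshold, digits = 3), ")")
    )
}

#' Plot eigenvector centralities
#'
#' @param object A `centrality_result`.
#' @param roster Optional roster used to colour the bars by sex.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot centrality_result
#' @export
autoplot.centrality_result <- function(object, roster = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(roster)) {
    d <- dplyr::left_join(d, roster[c("id", "sex")], by = "id")
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = stats::reorder(.data$id, -.data$centrality),
      y = .data$centrality, fill = .data$sex
    ))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = stats::reorder(.data$id, -.data$centrality), y = .data$centrality
    ))
  }
  p +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Eigenvector centrality") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the randomization-test null distribution
#'
#' Histogram of the resampled Welch t statistics with the observed t marked.
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(t = object$t_resampled), ggplot2::aes(x = .data$t)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$t_observed, colour = "red") +
    ggplot2::labs(
      x = "Resampled Welch t (female - male)", y = "Count",
      title = paste0(
        "Observed t = ", format(object$t_observed, digits = 4),
        ", two-sided p = ", format(object$p_two_sided, digits = 3)
      )
    ) +
    ggplot2::theme_minimal()
}
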