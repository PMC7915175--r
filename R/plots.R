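#' Plot a repeat landscape as stacked bars
#'
#' Percent-K divergence bins on the x axis, annotated coverage on the y
#' axis, one fill per class/family (or TE type after
#' [group_by_te_type()]). Low bins are recent copies, high bins ancient
#' ones, so peak position proxies the age of a transposition burst.
#'
#' @param object,x a `repeat_landscape`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.repeat_landscape <- function(object, ...) {
  ylab <- if (identical(attr(object, "normalization"), "percent"))
    "coverage (% of analyzed length)" else "coverage (bp)"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin, y = .data$value,
                               fill = .data$label)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "Kimura divergence to consensus (%K bin)", y = ylab,
                  fill = "class/family") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.repeat_landscape
#' @export
plot_landscape <- function(x, ...) autoplot.repeat_landscape(x, ...)

#' Plot a synteny net-graph
#'
#' Draws the BAC-chromosome graph with a force-directed layout: edges as
#' segments with width proportional to weight, chromosome nodes coloured by
#' species, BAC nodes in a single colour, labels on all nodes.
#'
#' @param graph a `synteny_graph`.
#' @param layout optional layout tibble from [layout_fruchterman()];
#'   computed with defaults when omitted.
#' @param ... passed to [layout_fruchterman()] when `layout` is `NULL`.
#' @return a ggplot object.
#' @export
plot_synteny_graph <- function(graph, layout = NULL, ...) {
  layout <- layout %||% layout_fruchterman(graph, ...)
  nodes <- dplyr::left_join(graph$nodes, layout[, c("id", "x", "y")],
                            by = "id")
  seg <- graph$edges |>
    left_join(layout[, c("id", "x", "y")], by = c(bac_id = "id")) |>
    left_join(layout[, c("id", "x", "y")], by = c(chromosome_id = "id"),
              suffix = c("", "_to"))
  nodes$colour <- ifelse(nodes$type == "BAC", "BAC", nodes$species)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, linewidth = .data$weight),
      colour = "grey70", alpha = 0.7) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$colour,
                   shape = .data$type), size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1, size = 2.8) +
    ggplot2::labs(colour = "node", shape = "type", linewidth = "genes") +
    ggplot2::theme_void()
}

#' Bar chart of a repeat summary
#'
#' @param summary a `repeat_summary` from [summarize_repeats()].
#' @param value `"coverage_pct"` or `"nl_per_mb"`.
#' @return a ggplot object.
#' @export
plot_repeat_summary <- function(summary, value = c("coverage_pct",
                                                   "nl_per_mb")) {
  value <- match.arg(value)
  df <- summary[summary$n_loci > 0 | summary[[value]] > 0, ]
  df$group_label <- factor(df$group_label, levels = rev(summary$group_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[value]],
                                   y = .data$group_label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = if (value == "coverage_pct") "coverage (%)" else
      "loci per Mb", y = NULL) +
    ggplot2::theme_minimal()
}
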