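#' Plot a phase space
#'
#' Draws the functional digraph with nodes placed by a force-directed
#' layout; periodic states are emphasized and colored by their
#' attractor, transient states drawn hollow.
#'
#' @param object a [enumerate_phase_space()] result.
#' @param labels draw state tuples next to the nodes (sensible only for
#'   small systems).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gds_phase_space
#' @export
autoplot.gds_phase_space <- function(object, labels = object$n <= 5, ...) {
  N <- object$r^object$n
  g <- igraph::graph_from_data_frame(
    data.frame(from = seq_len(N), to = object$successor + 1L),
    vertices = data.frame(name = seq_len(N)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(1)  # layout only; analysis results never depend on this
  xy <- igraph::layout_with_fr(g)
  tab <- tidy(object) |>
    dplyr::mutate(x = xy[, 1], y = xy[, 2],
                  attractor = factor(.data$attractor))
  seg <- tab |>
    dplyr::mutate(xend = .data$x[.data$successor + 1L],
                  yend = .data$y[.data$successor + 1L])
  p <- ggplot2::ggplot(tab, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(color = .data$attractor,
                                     shape = .data$periodic), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "periodic") +
    ggplot2::theme_void() +
    ggplot2::labs(color = "attractor")
  if (labels) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$state),
                                size = 2.5, vjust = -1)
  }
  p
}

#' Plot an attractor graph
#'
#' Nodes are attractors (labeled with their periods); arrows are
#' single-vertex perturbations leading from one basin to another.
#'
#' @param object a [build_attractor_graph()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot attractor_graph
#' @export
autoplot.attractor_graph <- function(object, ...) {
  m <- object$n_attractors
  ang <- 2 * pi * (seq_len(m) - 1) / m
  pos <- tibble::tibble(id = seq_len(m), x = cos(ang), y = sin(ang))
  periods <- vapply(object$ps$attractors, `[[`, integer(1), "period")
  e <- object$edges[object$edges$from != object$edges$to, ] |>
    dplyr::mutate(x = pos$x[.data$from], y = pos$y[.data$from],
                  xend = pos$x[.data$to], yend = pos$y[.data$to])
  ggplot2::ggplot(pos, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      data = e, ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm"), type = "closed"),
      color = "grey40",
      lineend = "round") +
    ggplot2::geom_point(size = 10, color = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("A%d\np=%d", .data$id, periods[.data$id])), size = 2.8) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
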