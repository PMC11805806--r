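#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_segment
#'   geom_label labs theme_minimal arrow unit scale_colour_manual
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' One line per species over time.
#'
#' @param object An `lv_trajectory` from [simulate_lv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lv_trajectory <- function(object, ...) {
  n <- ncol(object) - 1L
  long <- tidyr::pivot_longer(object, cols = -"time",
                              names_to = "species", values_to = "abundance")
  ggplot(long, aes(x = .data$time, y = .data$abundance,
                   colour = .data$species)) +
    geom_line() +
    labs(x = "time", y = "abundance", colour = "species") +
    theme_minimal()
}

#' Plot an invasion graph
#'
#' Nodes are admissible communities laid out by dimension (bottom: the empty
#' community, top: the largest ones); edges in any cycle (strongly connected
#' component of size above one) are drawn red.
#'
#' @param object An `lv_igraph` from [build_ig()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lv_igraph <- function(object, ...) {
  nodes <- object$nodes
  # deterministic layered layout: y = community dimension, x spreads ties
  nodes <- dplyr::arrange(nodes, .data$dim, .data$label)
  nodes <- dplyr::mutate(
    dplyr::group_by(nodes, .data$dim),
    x = seq_along(.data$label) - (dplyr::n() + 1) / 2
  )
  nodes <- dplyr::ungroup(nodes)
  pos <- setNames(seq_len(nrow(nodes)), nodes$label)
  comp <- igraph::components(object$graph, mode = "strong")
  member <- setNames(comp$membership, object$nodes$label)
  scc_size <- tabulate(comp$membership, nbins = comp$no)
  edges <- object$edges
  seg <- tibble::tibble(
    x = nodes$x[pos[edges$from]], y = nodes$dim[pos[edges$from]],
    xend = nodes$x[pos[edges$to]], yend = nodes$dim[pos[edges$to]],
    cyclic = vapply(seq_len(nrow(edges)), function(r) {
      member[[edges$from[r]]] == member[[edges$to[r]]] &&
        scc_size[member[[edges$from[r]]]] > 1L
    }, logical(1))
  )
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$cyclic),
                 arrow = arrow(length = unit(2, "mm")), alpha = 0.7) +
    geom_label(data = nodes,
               aes(x = .data$x, y = .data$dim, label = .data$label),
               size = 3) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                        guide = "none") +
    labs(x = NULL, y = "community size") +
    theme_minimal()
}

#' Plot a detector benchmark table
#'
#' Inconclusive rate against dimension.
#'
#' @param object An `lv_benchmark` from [detector_benchmark()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lv_benchmark <- function(object, ...) {
  ggplot(object, aes(x = .data$dim, y = .data$inconclusive_rate)) +
    geom_line() + geom_point() +
    labs(x = "dimension", y = "inconclusive rate") +
    theme_minimal()
}

#' Plot a cycle-density table
#'
#' Cycle density against the antisymmetric/symmetric norm ratio, one line per
#' dimension.
#'
#' @param object An `lv_cycle_density` from [cycle_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lv_cycle_density <- function(object, ...) {
  ggplot(object, aes(x = .data$ratio, y = .data$cycle_density,
                     colour = factor(.data$dim))) +
    geom_line() + geom_point() +
    labs(x = "|A_J| / |A_S|", y = "cycle density", colour = "dimension") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
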