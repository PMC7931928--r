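# The full pipeline: dependency network -> mutual-edge collapse -> MI
# scoring -> threshold selection -> cycle breaking -> orientation ->
# parameter fitting.

#' Refine a dependency network into a DAG
#'
#' Collapses mutual edges, scores every adjacency by pairwise mutual
#' information, selects the pruning threshold (automatically at the largest
#' adjacent gap of the sorted MI list, unless supplied), breaks directed
#' cycles shortest-first, and orients the remaining undirected edges.
#'
#' @param dn A [learn_dn()] result.
#' @param data The dataset the DN was learned from (used to score edges);
#'   may be omitted when `table` is supplied.
#' @param table Optional precomputed [score_all_edges()] table.
#' @param delta MI threshold in nats, or `"auto"` (default).
#' @param all_pairs Score all variable pairs rather than only adjacencies.
#' @return A list of class `refinement`: `graph` (fully directed
#'   `mixed_graph`), `table`, `delta`, `removals`, `orientations`.
#' @export
refine_structure <- function(dn, data = NULL, table = NULL, delta = "auto",
                             all_pairs = FALSE) {
  mg <- collapse_mutual_edges(dn)
  if (is.null(table)) {
    if (is.null(data)) {
      stop("either `data` or a precomputed `table` is required", call. = FALSE)
    }
    table <- score_all_edges(data, mg, all_pairs = all_pairs)
  }
  delta_obj <- if (identical(delta, "auto")) {
    if (nrow(table) == 0) new_delta(0, "auto") else select_delta(table)
  } else {
    new_delta(as.numeric(delta), "user")
  }
  pruned <- break_cycles(mg, table, delta_obj)
  oriented <- orient_edges(pruned, table, dn)
  structure(
    list(
      graph = oriented,
      table = table,
      delta = delta_obj,
      removals = attr(pruned, "removals"),
      orientations = attr(oriented, "orientations")
    ),
    class = "refinement"
  )
}

#' Learn a causal Bayesian network from discrete data
#'
#' Runs the full pipeline: learn a dependency network of depth-limited
#' probability trees (one per variable), collapse mutual edges, score
#' adjacencies by pairwise mutual information, break directed cycles
#' shortest-first by deleting weak edges, orient the remaining undirected
#' edges preserving acyclicity, and fit tree CPDs restricted to each node's
#' final parent set. The whole procedure is deterministic given the dataset
#' and configuration.
#'
#' @inheritParams learn_dn
#' @param delta MI pruning threshold in nats, or `"auto"` (default) to select
#'   it at the largest adjacent gap of the descending-sorted MI list.
#' @param all_pairs Score all variable pairs instead of only DN adjacencies.
#' @param param_depth Depth limit for the parameter-fitting phase; `NULL`
#'   (default) allows each node's tree to use all its parents.
#' @return A `causal_network` whose `report` field records the threshold
#'   used, the cycles broken (with the MI of each removed edge) and the
#'   orientation decisions. [tidy()] returns the edge tibble, [glance()] a
#'   one-row summary.
#' @examples
#' net <- bundled_network("demo6")
#' d <- forward_sample(net, 2000, seed = 1)
#' fit <- dn2cn(d)
#' tidy(fit)
#' @export
dn2cn <- function(data, ordering = NULL, delta = "auto", depth_limit = 2,
                  min_gain = 1e-3, min_samples_leaf = 5, alpha = 1,
                  all_pairs = FALSE, param_depth = NULL) {
  data <- as_discrete_data(data)
  dn <- learn_dn(data, ordering,
    depth_limit = depth_limit, min_gain = min_gain,
    min_samples_leaf = min_samples_leaf, alpha = alpha
  )
  ref <- refine_structure(dn, data = data, delta = delta, all_pairs = all_pairs)
  net <- fit_parameters(data, ref$graph, depth_limit = param_depth, alpha = alpha)
  net$report <- list(
    delta = as.numeric(ref$delta),
    delta_provenance = attr(ref$delta, "provenance"),
    dn_edges = dn$edges,
    n_cycles = length(unique(ref$removals$cycle)),
    removals = ref$removals,
    orientations = ref$orientations
  )
  net
}

#' Plot a learned or ground-truth network
#'
#' Draws nodes on a circle with directed edges as arrows (and undirected
#' edges, if any, as plain segments). Deterministic layout.
#'
#' @param object A `causal_network`, `mixed_graph`, `dependency_network` or
#'   `ground_truth_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.causal_network <- function(object, ...) {
  plot_edges(object$variables, new_edge_tibble(
    object$edges$from, object$edges$to, "directed"
  ))
}

#' @rdname autoplot.causal_network
#' @export
autoplot.mixed_graph <- function(object, ...) {
  plot_edges(object$variables, object$edges)
}

#' @rdname autoplot.causal_network
#' @export
autoplot.dependency_network <- function(object, ...) {
  plot_edges(object$variables, new_edge_tibble(
    object$edges$from, object$edges$to, "directed"
  ))
}

#' @rdname autoplot.causal_network
#' @export
autoplot.ground_truth_network <- function(object, ...) {
  e <- network_edges(object)
  plot_edges(object$variables, new_edge_tibble(e$from, e$to, "directed"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

plot_edges <- function(variables, edges) {
  vars <- sort(variables)
  k <- length(vars)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  nodes <- tibble::tibble(
    name = vars, x = cos(theta), y = sin(theta)
  )
  seg <- dplyr::left_join(edges, nodes, by = c("from" = "name"))
  seg <- dplyr::left_join(seg, nodes,
    by = c("to" = "name"), suffix = c("", "end")
  )
  # stop arrows short of the node label
  shrink <- 0.12
  dx <- seg$xend - seg$x
  dy <- seg$yend - seg$y
  len <- sqrt(dx^2 + dy^2)
  len[len == 0] <- 1
  seg$x <- seg$x + shrink * dx / len
  seg$y <- seg$y + shrink * dy / len
  seg$xend <- seg$xend - shrink * dx / len
  seg$yend <- seg$yend - shrink * dy / len
  p <- ggplot2::ggplot()
  if (nrow(seg) > 0) {
    dirseg <- seg[seg$mark == "directed", ]
    undseg <- seg[seg$mark == "undirected", ]
    if (nrow(dirseg) > 0) {
      p <- p + ggplot2::geom_segment(
        data = dirseg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
        arrow = grid::arrow(length = grid::unit(0.15, "inches")),
        colour = "grey30"
      )
    }
    if (nrow(undseg) > 0) {
      p <- p + ggplot2::geom_segment(
        data = undseg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
        linetype = "dashed", colour = "grey50"
      )
    }
  }
  p +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name)
    ) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void()
}
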