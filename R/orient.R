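# Orientation of the undirected edges that remain after cycle breaking.
#
# Edges are processed in descending MI order. Acyclicity decides whenever it
# can; otherwise an asymmetry of the dependency network's trees is used:
# orient X -> Y when X's own tree tests Y at a shallower depth than Y's tree
# tests X. A variable with no parents of its own recruits its dependent child
# near the root of its tree, while the child reaches this partner only under
# its stronger direct parents, so the variable testing its partner nearer its
# own root is treated as upstream. Remaining ties are resolved by a fixed
# name convention (from the lexicographically later variable to the earlier).

has_directed_path <- function(edges, from, to) {
  if (from == to) {
    return(TRUE)
  }
  frontier <- from
  seen <- character(0)
  while (length(frontier) > 0) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    if (to %in% nxt) {
      return(TRUE)
    }
    seen <- c(seen, frontier)
    frontier <- setdiff(nxt, seen)
  }
  FALSE
}

#' Orient undirected edges preserving acyclicity
#'
#' Processes the undirected edges in descending MI order. For each edge, if
#' only one direction keeps the directed part acyclic, that direction is
#' taken; when both do, the direction is chosen from the dependency network's
#' tree CPDs (the variable whose own tree tests the other at the shallower
#' depth becomes the parent), with remaining ties broken by a fixed
#' lexicographic convention. The directed part of `graph` must already be
#' acyclic.
#'
#' @param graph A `mixed_graph` whose directed part is acyclic (e.g. a
#'   [break_cycles()] result).
#' @param table A [score_all_edges()] result covering the undirected edges.
#' @param dn The [learn_dn()] result the graph descends from (source of the
#'   tree CPDs); may be omitted when `graph` carries the trees.
#' @return A `mixed_graph` with no undirected edges and an acyclic directed
#'   edge set; the choices made are recorded in the `orientations` attribute.
#' @export
orient_edges <- function(graph, table, dn = NULL) {
  stopifnot(inherits(graph, "mixed_graph"))
  trees <- if (!is.null(dn)) dn$trees else graph$trees
  und <- undirected_edges(graph)
  dir_edges <- directed_edges(graph)
  if (!edges_acyclic(dir_edges, graph$variables)) {
    stop("the directed part of the graph must be acyclic before orientation",
      call. = FALSE
    )
  }
  if (nrow(und) == 0) {
    attr(graph, "orientations") <- orientation_log()
    return(graph)
  }
  und$mi <- mi_lookup(table, und$from, und$to)
  und <- dplyr::arrange(und, dplyr::desc(.data$mi), .data$from, .data$to)

  log_rows <- list()
  for (i in seq_len(nrow(und))) {
    a <- und$from[i]
    b <- und$to[i]
    ab_ok <- !has_directed_path(dir_edges, b, a)
    ba_ok <- !has_directed_path(dir_edges, a, b)
    if (!ab_ok && !ba_ok) {
      stop("internal error: neither orientation of ", a, " -- ", b,
        " preserves acyclicity",
        call. = FALSE
      )
    }
    if (ab_ok && !ba_ok) {
      from <- a
      to <- b
      reason <- "acyclicity"
    } else if (ba_ok && !ab_ok) {
      from <- b
      to <- a
      reason <- "acyclicity"
    } else {
      d_ab <- if (!is.null(trees) && a %in% names(trees)) {
        tree_test_depth(trees[[a]], b)
      } else {
        Inf
      }
      d_ba <- if (!is.null(trees) && b %in% names(trees)) {
        tree_test_depth(trees[[b]], a)
      } else {
        Inf
      }
      if (d_ab < d_ba) {
        from <- a
        to <- b
        reason <- "tree_depth"
      } else if (d_ba < d_ab) {
        from <- b
        to <- a
        reason <- "tree_depth"
      } else {
        from <- max(a, b)
        to <- min(a, b)
        reason <- "lexicographic"
      }
    }
    dir_edges <- dplyr::bind_rows(dir_edges, tibble::tibble(from = from, to = to))
    log_rows[[i]] <- tibble::tibble(
      a = a, b = b, mi = und$mi[i], from = from, to = to, reason = reason
    )
  }
  out <- new_mixed_graph(
    graph$variables,
    dplyr::arrange(
      new_edge_tibble(dir_edges$from, dir_edges$to, "directed"),
      .data$from, .data$to
    ),
    trees
  )
  stopifnot(edges_acyclic(directed_edges(out), out$variables))
  attr(out, "orientations") <- dplyr::bind_rows(log_rows)
  out
}

orientation_log <- function() {
  tibble::tibble(
    a = character(0), b = character(0), mi = numeric(0),
    from = character(0), to = character(0), reason = character(0)
  )
}
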