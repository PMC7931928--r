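# Directed-cycle detection (shortest first) and MI-guided cycle breaking.
# Only directed edges participate in cycles; undirected edges are handled at
# the orientation stage.

adjacency_list <- function(edges, variables) {
  adj <- lapply(variables, function(v) sort(edges$to[edges$from == v]))
  names(adj) <- variables
  adj
}

in_list <- function(edges, variables) {
  adj <- lapply(variables, function(v) sort(edges$from[edges$to == v]))
  names(adj) <- variables
  adj
}

#' Find a minimum-length directed cycle
#'
#' Runs a breadth-first search from every node over the directed edges and
#' keeps the globally shortest directed cycle. Among equal-length cycles the
#' one whose lexicographically-smallest-rotation node sequence sorts first is
#' returned, so the result is deterministic.
#'
#' @param graph A `mixed_graph` (only its directed edges are considered) or a
#'   `dependency_network`.
#' @return A character vector of node names `c(v1, ..., vk)` describing the
#'   cycle `v1 -> v2 -> ... -> vk -> v1`, or `NULL` when the directed part is
#'   acyclic.
#' @export
find_shortest_cycle <- function(graph) {
  if (inherits(graph, "dependency_network")) graph <- collapse_mutual_edges(graph)
  edges <- directed_edges(graph)
  vars <- sort(graph$variables)
  if (nrow(edges) == 0) {
    return(NULL)
  }
  adj <- adjacency_list(edges, vars)
  inn <- in_list(edges, vars)

  bfs_dist <- function(start, neigh) {
    dist <- stats::setNames(rep(Inf, length(vars)), vars)
    dist[start] <- 0
    queue <- start
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in neigh[[u]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[u] + 1
          queue <- c(queue, w)
        }
      }
    }
    dist
  }

  # pass 1: the global minimum cycle length
  best_len <- Inf
  dists <- list()
  for (v in vars) {
    if (length(inn[[v]]) == 0 || length(adj[[v]]) == 0) next
    dists[[v]] <- bfs_dist(v, adj)
    reach <- dists[[v]][inn[[v]]]
    if (any(is.finite(reach))) best_len <- min(best_len, min(reach) + 1)
  }
  if (is.infinite(best_len)) {
    return(NULL)
  }

  # pass 2: among all cycles of minimal length, reconstruct for every closing
  # edge (u -> v) the lexicographically smallest shortest path v -> u and keep
  # the smallest canonical rotation overall
  best <- NULL
  best_key <- NULL
  for (v in vars) {
    if (is.null(dists[[v]])) next
    for (u in inn[[v]]) {
      if (!is.finite(dists[[v]][u]) || dists[[v]][u] + 1 != best_len) next
      to_u <- bfs_dist(u, inn) # distance of every node TO u
      path <- v
      cur <- v
      while (cur != u) {
        nxt <- adj[[cur]][to_u[adj[[cur]]] == to_u[cur] - 1]
        cur <- nxt[1] # sorted adjacency: lexicographically smallest step
        path <- c(path, cur)
      }
      cyc <- canonical_rotation(unname(path))
      key <- paste(cyc, collapse = "\r")
      if (is.null(best_key) || key < best_key) {
        best <- cyc
        best_key <- key
      }
    }
  }
  best
}

canonical_rotation <- function(nodes) {
  i <- which(nodes == min(nodes))[1]
  if (i == 1) {
    return(nodes)
  }
  c(nodes[i:length(nodes)], nodes[seq_len(i - 1)])
}

cycle_edges <- function(cycle) {
  tibble::tibble(from = cycle, to = c(cycle[-1], cycle[1]))
}

#' Break directed cycles by deleting weak edges
#'
#' Repeatedly finds a shortest directed cycle and deletes every edge on it
#' whose mutual information is at or below `delta`; when no edge on the cycle
#' falls below the threshold, the single minimum-MI edge of the cycle is
#' deleted instead so the loop always terminates. Undirected edges are never
#' touched.
#'
#' @param graph A `mixed_graph` whose edges are covered by `table`.
#' @param table A [score_all_edges()] result.
#' @param delta MI threshold in nats (a number or [select_delta()] result).
#' @return The pruned `mixed_graph`; the deletions are recorded in the
#'   `removals` attribute (a tibble with columns `from`, `to`, `mi`, `rule`
#'   and `cycle`).
#' @export
break_cycles <- function(graph, table, delta) {
  stopifnot(inherits(graph, "mixed_graph"))
  delta <- as.numeric(delta)
  log_rows <- list()
  repeat {
    cyc <- find_shortest_cycle(graph)
    if (is.null(cyc)) break
    ce <- cycle_edges(cyc)
    ce$mi <- mi_lookup(table, ce$from, ce$to)
    drop <- which(ce$mi <= delta)
    rule <- "below_delta"
    if (length(drop) == 0) {
      # deterministic fallback: the cycle's weakest edge (lex on ties)
      ord <- order(ce$mi, ce$from, ce$to)
      drop <- ord[1]
      rule <- "fallback_min"
    }
    removed <- ce[drop, ]
    removed$rule <- rule
    removed$cycle <- paste(c(cyc, cyc[1]), collapse = " -> ")
    log_rows[[length(log_rows) + 1]] <- removed
    key <- paste(graph$edges$from, graph$edges$to, sep = "\r")
    graph$edges <- graph$edges[!(key %in% paste(removed$from, removed$to, sep = "\r") &
      graph$edges$mark == "directed"), ]
  }
  removals <- if (length(log_rows) > 0) {
    dplyr::bind_rows(log_rows)
  } else {
    tibble::tibble(
      from = character(0), to = character(0), mi = numeric(0),
      rule = character(0), cycle = character(0)
    )
  }
  attr(graph, "removals") <- removals
  graph
}

# TRUE when the directed edge set admits a topological order.
edges_acyclic <- function(edges, variables) {
  if (nrow(edges) == 0) {
    return(TRUE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = variables)
  igraph::is_dag(g)
}

topological_order <- function(edges, variables) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = TRUE, vertices = sort(variables)
  )
  names(igraph::topo_sort(g, mode = "out"))
}
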