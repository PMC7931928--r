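# Dependency networks: one tree CPD per variable, learned independently, with
# the directed (possibly cyclic) edge set parent -> variable.

new_edge_tibble <- function(from = character(0), to = character(0),
                            mark = character(0)) {
  tibble::tibble(from = from, to = to, mark = mark)
}

#' Learn a dependency network
#'
#' Fits one depth-limited probability tree per variable, each conditioned on
#' all other variables (optionally restricted by a variable ordering), and
#' assembles the directed edge set `parent -> variable` from the tree parent
#' sets. Because the conditionals are learned independently, the resulting
#' graph may contain directed cycles and mutual pairs `X -> Y`, `Y -> X`; see
#' [collapse_mutual_edges()].
#'
#' When an ordering covers a variable, its candidate parents are restricted to
#' variables listed earlier in the ordering; variables absent from a partial
#' ordering are unconstrained (both as parents and as targets).
#'
#' @inheritParams learn_tree
#' @param ordering Optional character vector of variable names, earliest
#'   first (an allowed-ancestor constraint), or `NULL`.
#' @return An object of class `dependency_network` with fields `variables`,
#'   `edges` (tibble with columns `from`, `to`) and `trees` (named list of
#'   [learn_tree()] results).
#' @examples
#' d <- data.frame(
#'   x = rep(c("0", "1"), each = 50),
#'   y = rep(c("0", "1"), each = 50)
#' )
#' learn_dn(d)$edges
#' @export
learn_dn <- function(data, ordering = NULL, depth_limit = 2, min_gain = 1e-3,
                     min_samples_leaf = 5, alpha = 1) {
  data <- as_discrete_data(data)
  vars <- variables(data)
  check_ordering(ordering, data)

  trees <- lapply(vars, function(v) {
    cands <- setdiff(vars, v)
    if (!is.null(ordering) && v %in% ordering) {
      pos <- match(v, ordering)
      allowed <- c(ordering[seq_len(pos - 1)], setdiff(vars, ordering))
      cands <- intersect(cands, allowed)
    }
    learn_tree(data, v, cands,
      depth_limit = depth_limit, min_gain = min_gain,
      min_samples_leaf = min_samples_leaf, alpha = alpha
    )
  })
  names(trees) <- vars

  edges <- purrr::map_dfr(vars, function(v) {
    pa <- tree_parents(trees[[v]])
    if (length(pa) == 0) {
      return(tibble::tibble(from = character(0), to = character(0)))
    }
    tibble::tibble(from = pa, to = v)
  })
  edges <- dplyr::arrange(edges, .data$from, .data$to)

  structure(
    list(variables = vars, edges = edges, trees = trees),
    class = "dependency_network"
  )
}

#' @export
print.dependency_network <- function(x, ...) {
  mut <- mutual_pairs(x$edges)
  cat(sprintf(
    "<dependency_network> %d variables, %d directed edges (%d mutual pairs)\n",
    length(x$variables), nrow(x$edges), nrow(mut)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.dependency_network <- function(x, ...) {
  x$edges
}

# Unordered pairs connected in both directions; columns a < b.
mutual_pairs <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble::tibble(a = character(0), b = character(0)))
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  rev_key <- paste(edges$to, edges$from, sep = "\r")
  both <- edges[key %in% rev_key & edges$from < edges$to, c("from", "to")]
  tibble::tibble(a = both$from, b = both$to)
}

#' Collapse mutual edges to undirected ones
#'
#' Every pair of variables connected in both directions becomes a single
#' undirected edge; single-direction edges stay directed. The tree CPDs are
#' carried along unchanged. The operation is idempotent and preserves the
#' adjacency structure (skeleton) exactly.
#'
#' @param dn A [learn_dn()] result (or a `mixed_graph`, returned unchanged
#'   apart from re-collapsing, which is a no-op).
#' @return An object of class `mixed_graph` with an `edges` tibble holding
#'   columns `from`, `to` and `mark` (`"directed"` or `"undirected"`;
#'   undirected rows are stored once with `from < to`).
#' @export
collapse_mutual_edges <- function(dn) {
  if (inherits(dn, "mixed_graph")) {
    return(dn)
  }
  stopifnot(inherits(dn, "dependency_network"))
  edges <- dn$edges
  mut <- mutual_pairs(edges)
  if (nrow(mut) > 0) {
    mut_key <- c(
      paste(mut$a, mut$b, sep = "\r"),
      paste(mut$b, mut$a, sep = "\r")
    )
    keep <- !(paste(edges$from, edges$to, sep = "\r") %in% mut_key)
    out <- dplyr::bind_rows(
      new_edge_tibble(edges$from[keep], edges$to[keep], "directed"),
      new_edge_tibble(mut$a, mut$b, "undirected")
    )
  } else {
    out <- new_edge_tibble(edges$from, edges$to, rep("directed", nrow(edges)))
  }
  out <- dplyr::arrange(out, .data$from, .data$to)
  new_mixed_graph(dn$variables, out, dn$trees)
}

new_mixed_graph <- function(variables, edges, trees = NULL) {
  stopifnot(all(c("from", "to", "mark") %in% names(edges)))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
  structure(
    list(variables = variables, edges = tibble::as_tibble(edges), trees = trees),
    class = "mixed_graph"
  )
}

#' @export
print.mixed_graph <- function(x, ...) {
  nd <- sum(x$edges$mark == "directed")
  nu <- sum(x$edges$mark == "undirected")
  cat(sprintf(
    "<mixed_graph> %d variables, %d directed + %d undirected edges\n",
    length(x$variables), nd, nu
  ))
  invisible(x)
}

#' @export
tidy.mixed_graph <- function(x, ...) {
  x$edges
}

directed_edges <- function(graph) {
  graph$edges[graph$edges$mark == "directed", c("from", "to")]
}

undirected_edges <- function(graph) {
  graph$edges[graph$edges$mark == "undirected", c("from", "to")]
}
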