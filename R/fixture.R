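# A hand-constructed six-variable dependency network and MI score table for
# the worked example: a shortest cycle A -> C -> B -> A whose weakest edge
# A -> C is pruned, and two mutual pairs (B--D, E--F) oriented afterwards.
#
# The fixture is constructed rather than learned: a greedy
# information-gain learner cannot produce this exact configuration from any
# sample, because C's tree testing A (and not B) requires MI(A,C) > MI(B,C),
# while pruning A -> C and keeping C -> B requires the opposite inequality.
# The fixture therefore encodes tree structures and MI values directly,
# consistent with the decisions the worked example walks through.

manual_leaf <- function(p_yes, n) {
  prob <- c("0" = 1 - p_yes, "1" = p_yes)
  list(leaf = TRUE, prob = prob, n = n, counts = round(n * prob))
}

manual_split <- function(var, children, n) {
  list(leaf = FALSE, var = var, values = c("0", "1"), children = children, n = n)
}

manual_tree <- function(target, node, depth_limit = 2) {
  structure(
    list(
      target = target, node = node, levels = c("0", "1"),
      depth_limit = depth_limit, min_gain = 1e-3, min_samples_leaf = 5,
      alpha = 1
    ),
    class = "tree_cpd"
  )
}

#' Six-variable worked-example fixture
#'
#' A small dependency network over variables `A`–`F` containing one directed
#' three-cycle (`A -> C -> B -> A`), two mutual pairs (`B`/`D` and `E`/`F`)
#' and one extra directed edge (`B -> E`), together with a mutual-information
#' score table in which the `A`–`C` adjacency is by far the weakest. Running
#' the refinement pipeline on it collapses the mutual pairs, auto-selects the
#' threshold at the largest gap of the sorted MI list (0.02), removes
#' `A -> C` from the cycle, and orients `D -> B` and `F -> E`, producing the
#' DAG `B -> A, C -> B, D -> B, B -> E, F -> E`.
#'
#' @return A list with elements `dn` (a `dependency_network`), `mi` (an MI
#'   score table) and `dag` (the expected final edge tibble).
#' @seealso [bundled_network()] for the matching generative network
#'   (`"demo6"`).
#' @export
demo_network_fixture <- function() {
  trees <- list(
    A = manual_tree("A", manual_split("B", list(
      manual_leaf(0.15, 500), manual_leaf(0.90, 500)
    ), 1000)),
    B = manual_tree("B", manual_split("D", list(
      manual_split("C", list(manual_leaf(0.10, 250), manual_leaf(0.80, 250)), 500),
      manual_split("C", list(manual_leaf(0.75, 250), manual_leaf(0.95, 250)), 500)
    ), 1000)),
    C = manual_tree("C", manual_split("A", list(
      manual_leaf(0.45, 500), manual_leaf(0.55, 500)
    ), 1000)),
    D = manual_tree("D", manual_split("B", list(
      manual_leaf(0.25, 500), manual_leaf(0.75, 500)
    ), 1000)),
    E = manual_tree("E", manual_split("F", list(
      manual_split("B", list(manual_leaf(0.05, 250), manual_leaf(0.75, 250)), 500),
      manual_split("B", list(manual_leaf(0.70, 250), manual_leaf(0.95, 250)), 500)
    ), 1000)),
    F = manual_tree("F", manual_split("E", list(
      manual_leaf(0.20, 500), manual_leaf(0.80, 500)
    ), 1000))
  )
  vars <- names(trees)
  edges <- purrr::map_dfr(vars, function(v) {
    pa <- tree_parents(trees[[v]])
    if (length(pa) == 0) {
      return(tibble::tibble(from = character(0), to = character(0)))
    }
    tibble::tibble(from = pa, to = v)
  })
  dn <- structure(
    list(
      variables = vars,
      edges = dplyr::arrange(edges, .data$from, .data$to),
      trees = trees
    ),
    class = "dependency_network"
  )
  mi <- tibble::tibble(
    x = c("E", "B", "A", "B", "B", "A"),
    y = c("F", "D", "B", "E", "C", "C"),
    mi = c(0.30, 0.25, 0.20, 0.15, 0.12, 0.02)
  )
  class(mi) <- c("mi_score_table", class(mi))
  dag <- tibble::tibble(
    from = c("B", "B", "C", "D", "F"),
    to = c("A", "E", "B", "B", "E")
  )
  list(dn = dn, mi = mi, dag = dag)
}
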