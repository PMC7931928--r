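# Parameter fitting (tree CPDs restricted to final parent sets), joint
# log-likelihood, and forward sampling.

#' Fit tree CPDs for a fixed DAG
#'
#' For every node a probability tree is learned with candidates restricted to
#' the node's parents in the DAG. The parameter-phase depth limit defaults to
#' the number of parents so that full conditioning is reachable (distinct
#' from the shallower structure-phase depth), and the gain floor defaults to
#' zero so every informative parent is used; with `alpha = 0` the leaves hold
#' raw maximum-likelihood frequencies.
#'
#' @inheritParams learn_tree
#' @param dag A DAG: a `causal_network`, a `mixed_graph` with no undirected
#'   edges, or an edge tibble/data frame with columns `from`, `to`.
#' @param depth_limit Parameter-phase depth limit; `NULL` (default) means the
#'   number of parents of each node.
#' @param min_samples_leaf Minimum node size to attempt a split (default 1 in
#'   the parameter phase: estimation should reach every parent
#'   configuration present in the data).
#' @return An object of class `causal_network`.
#' @export
fit_parameters <- function(data, dag, depth_limit = NULL, min_gain = 0,
                           min_samples_leaf = 1, alpha = 1) {
  data <- as_discrete_data(data)
  edges <- dag_edges(dag)
  vars <- variables(data)
  extra <- setdiff(unique(c(edges$from, edges$to)), vars)
  if (length(extra) > 0) {
    stop("DAG mentions variables absent from the dataset: ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  if (!edges_acyclic(edges, vars)) {
    stop("`dag` must be acyclic", call. = FALSE)
  }
  trees <- lapply(vars, function(v) {
    parents <- sort(edges$from[edges$to == v])
    learn_tree(data, v, parents,
      depth_limit = if (is.null(depth_limit)) length(parents) else depth_limit,
      min_gain = min_gain, min_samples_leaf = min_samples_leaf, alpha = alpha
    )
  })
  names(trees) <- vars
  new_causal_network(
    variables = vars,
    edges = dplyr::arrange(edges[, c("from", "to")], .data$from, .data$to),
    trees = trees,
    levels = data$levels
  )
}

dag_edges <- function(dag) {
  if (inherits(dag, "causal_network")) {
    return(dag$edges)
  }
  if (inherits(dag, "ground_truth_network")) {
    return(network_edges(dag))
  }
  if (inherits(dag, "mixed_graph")) {
    if (nrow(undirected_edges(dag)) > 0) {
      stop("the graph still contains undirected edges; orient them first",
        call. = FALSE
      )
    }
    return(directed_edges(dag))
  }
  if (is.data.frame(dag)) {
    stopifnot(all(c("from", "to") %in% names(dag)))
    return(tibble::as_tibble(dag[, c("from", "to")]))
  }
  stop("cannot interpret `dag` as a directed acyclic graph", call. = FALSE)
}

new_causal_network <- function(variables, edges, trees, levels, report = NULL) {
  structure(
    list(
      variables = variables, edges = tibble::as_tibble(edges),
      trees = trees, levels = levels, report = report
    ),
    class = "causal_network"
  )
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf(
    "<causal_network> %d variables, %d directed edges\n",
    length(x$variables), nrow(x$edges)
  ))
  if (nrow(x$edges) > 0) {
    cat(paste(sprintf("  %s -> %s", x$edges$from, x$edges$to), collapse = "\n"),
      "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
tidy.causal_network <- function(x, ...) {
  x$edges
}

#' @export
glance.causal_network <- function(x, ...) {
  rep <- x$report
  tibble::tibble(
    n_variables = length(x$variables),
    n_edges = nrow(x$edges),
    delta = if (is.null(rep)) NA_real_ else as.numeric(rep$delta),
    delta_provenance = if (is.null(rep)) NA_character_ else rep$delta_provenance,
    n_cycles_broken = if (is.null(rep)) NA_integer_ else rep$n_cycles,
    n_edges_removed = if (is.null(rep)) NA_integer_ else nrow(rep$removals)
  )
}

#' Joint log-likelihood of a dataset under a network
#'
#' Sums, over rows and variables, the log probability of the observed state
#' under each node's conditional (the leaf reached by the row for tree CPDs,
#' the matching table row for table CPDs). With unsmoothed (maximum
#' likelihood, `alpha = 0`) leaves a zero-probability observation yields
#' `-Inf` with a warning rather than an error.
#'
#' @inheritParams learn_tree
#' @param net A `causal_network` or `ground_truth_network` whose variables
#'   and state spaces match the dataset.
#' @param base Logarithm base; default natural log (nats).
#' @return A single number.
#' @export
log_likelihood <- function(data, net, base = exp(1)) {
  data <- as_discrete_data(data)
  UseMethod("log_likelihood", net)
}

#' @export
log_likelihood.causal_network <- function(data, net, base = exp(1)) {
  data <- as_discrete_data(data)
  check_states(data, net$levels)
  total <- 0
  for (v in net$variables) {
    total <- total + tree_loglik(net$trees[[v]], data, v)
  }
  if (is.infinite(total)) {
    warning(
      "zero-probability observation under unsmoothed leaves; ",
      "log-likelihood is -Inf",
      call. = FALSE
    )
  }
  total / log(base)
}

#' @export
log_likelihood.ground_truth_network <- function(data, net, base = exp(1)) {
  data <- as_discrete_data(data)
  check_states(data, net$levels)
  total <- 0
  for (v in net$variables) {
    probs <- cpd_row_probs(net, v, data)
    total <- total + sum(log(probs))
  }
  if (is.infinite(total)) {
    warning("zero-probability observation; log-likelihood is -Inf",
      call. = FALSE
    )
  }
  total / log(base)
}

check_states <- function(data, levels) {
  for (v in names(levels)) {
    if (!v %in% variables(data)) {
      stop("dataset is missing variable '", v, "'", call. = FALSE)
    }
    if (!all(data$levels[[v]] %in% levels[[v]])) {
      stop("dataset has states unknown to the network for variable '", v, "'",
        call. = FALSE
      )
    }
  }
}

# Sum of log P(target | path leaf) over all rows, natural log.
tree_loglik <- function(tree, data, target) {
  # recode the dataset's codes into the tree's level order
  recode <- function(v, tree_levels) {
    match(data$levels[[v]], tree_levels)[data$codes[, v]]
  }
  tcode <- recode(target, tree$levels)
  walk <- function(node, idx) {
    if (length(idx) == 0) {
      return(0)
    }
    if (node$leaf) {
      return(sum(log(node$prob[tcode[idx]])))
    }
    vcode <- recode(node$var, node$values)
    sum(vapply(
      seq_along(node$values),
      function(s) walk(node$children[[s]], idx[vcode[idx] == s]),
      numeric(1)
    ))
  }
  walk(tree$node, seq_len(data$m))
}

#' Forward-sample a dataset from a network
#'
#' Samples variables in topological order, each from its conditional given
#' the already-sampled parent values. Reproducible given `seed`.
#'
#' @param net A `causal_network` (tree CPDs) or `ground_truth_network` (table
#'   CPDs).
#' @param n Number of samples (rows) to draw.
#' @param seed Optional integer seed.
#' @return A tibble of factor columns; every column keeps the network's full
#'   state set as factor levels, so rare unseen states do not change arities.
#' @export
forward_sample <- function(net, n, seed = NULL) {
  UseMethod("forward_sample")
}

#' @export
forward_sample.ground_truth_network <- function(net, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  order <- topological_order(network_edges(net), net$variables)
  order <- c(order, setdiff(net$variables, order))
  codes <- matrix(NA_integer_, nrow = n, ncol = length(net$variables),
    dimnames = list(NULL, net$variables)
  )
  for (v in order) {
    probs <- cpd_config_matrix(net, v) # configs x states
    idx <- config_index(net, v, codes)
    codes[, v] <- sample_rows(probs[idx, , drop = FALSE])
  }
  codes_to_tibble(codes, net$levels)
}

#' @export
forward_sample.causal_network <- function(net, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  order <- topological_order(net$edges, net$variables)
  order <- c(order, setdiff(net$variables, order))
  codes <- matrix(NA_integer_, nrow = n, ncol = length(net$variables),
    dimnames = list(NULL, net$variables)
  )
  for (v in order) {
    tree <- net$trees[[v]]
    codes[, v] <- sample_tree(tree, net$levels, codes, seq_len(n))
  }
  codes_to_tibble(codes, net$levels)
}

# Route rows through the tree, sampling at each leaf (codes are in the
# network's level order).
sample_tree <- function(tree, levels, codes, idx) {
  out <- integer(nrow(codes))
  walk <- function(node, idx) {
    if (length(idx) == 0) {
      return(invisible())
    }
    if (node$leaf) {
      p <- node$prob[match(levels[[tree$target]], names(node$prob))]
      out[idx] <<- sample_rows(matrix(p,
        nrow = length(idx), ncol = length(p),
        byrow = TRUE
      ))
      return(invisible())
    }
    # position of each row's state among the node's branch values
    inv <- match(levels[[node$var]], node$values)
    vcode <- inv[codes[idx, node$var]]
    for (s in seq_along(node$values)) {
      walk(node$children[[s]], idx[vcode == s])
    }
    invisible()
  }
  walk(tree$node, idx)
  out
}

# One categorical draw per row of a probability matrix (rows sum to 1).
sample_rows <- function(p) {
  if (ncol(p) == 1) {
    return(rep(1L, nrow(p)))
  }
  cum <- t(apply(p, 1, cumsum))
  u <- stats::runif(nrow(p)) * cum[, ncol(cum)]
  1L + as.integer(rowSums(u > cum[, -ncol(cum), drop = FALSE]))
}

codes_to_tibble <- function(codes, levels) {
  cols <- lapply(colnames(codes), function(v) {
    factor(levels[[v]][codes[, v]], levels = levels[[v]])
  })
  names(cols) <- colnames(codes)
  tibble::as_tibble(cols)
}
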