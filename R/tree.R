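# Depth-limited probability trees (tree-structured CPDs).
#
# Interior nodes test one variable with one branch per state; leaves hold an
# add-alpha smoothed categorical distribution over the target's states plus
# the number of training samples that reached them. The set of variables
# tested anywhere in the tree is the learned parent set: regularities in the
# conditional (context-specific independence) keep irrelevant variables out.

entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) {
    return(0)
  }
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# Information gain of splitting `idx` rows on candidate `cand` (node-local,
# natural log): H(target) - sum_s (n_s/n) H(target | cand = s), on raw counts.
split_gain <- function(tcode, ccode, idx, t_arity, c_arity) {
  tc <- tcode[idx]
  cc <- ccode[idx]
  n <- length(idx)
  joint <- matrix(tabulate((cc - 1L) * t_arity + tc, nbins = t_arity * c_arity),
    nrow = t_arity
  )
  h0 <- entropy_counts(rowSums(joint))
  hc <- 0
  for (s in seq_len(c_arity)) {
    ns <- sum(joint[, s])
    if (ns > 0) hc <- hc + (ns / n) * entropy_counts(joint[, s])
  }
  h0 - hc
}

#' Learn a depth-limited probability tree for one variable
#'
#' Greedy top-down induction: at each node the candidate variable maximising
#' the information gain (entropy reduction in nats, computed on the node's
#' samples) is chosen as the test. Growth stops when the depth limit is
#' reached, the best gain falls below `min_gain`, or the node holds fewer than
#' `min_samples_leaf` samples. Leaves carry add-`alpha` smoothed conditional
#' distributions over the target's states. Ties on the gain are broken by
#' lexicographic variable name, so the procedure is deterministic and
#' invariant to row order.
#'
#' @param data A data frame or [as_discrete_data()] object.
#' @param target Name of the target variable.
#' @param candidates Character vector of candidate test variables (must not
#'   contain `target`). An empty candidate set yields a single-leaf tree
#'   holding the target's smoothed marginal.
#' @param depth_limit Maximum number of tests on any root-to-leaf path.
#' @param min_gain Minimum information gain (nats) required to split a node.
#' @param min_samples_leaf Nodes with fewer samples are not split.
#' @param alpha Laplace pseudo-count added to every target state at a leaf;
#'   `alpha = 0` gives the raw maximum-likelihood frequencies.
#' @return An object of class `tree_cpd`.
#' @seealso [predict_distribution()], [tree_parents()]
#' @export
learn_tree <- function(data, target, candidates = NULL,
                       depth_limit = 2, min_gain = 1e-3,
                       min_samples_leaf = 5, alpha = 1) {
  data <- as_discrete_data(data)
  vars <- variables(data)
  if (!target %in% vars) stop("unknown target variable: ", target, call. = FALSE)
  if (is.null(candidates)) candidates <- setdiff(vars, target)
  if (target %in% candidates) {
    stop("the target must not appear among the candidates", call. = FALSE)
  }
  unknown <- setdiff(candidates, vars)
  if (length(unknown) > 0) {
    stop("unknown candidate variable(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(depth_limit >= 0, data$m >= 1, alpha >= 0)
  candidates <- sort(candidates)

  codes <- data$codes
  arity <- data$arity
  t_arity <- arity[[target]]
  t_levels <- data$levels[[target]]
  tcode <- codes[, target]

  make_leaf <- function(idx) {
    counts <- tabulate(tcode[idx], nbins = t_arity)
    tot <- sum(counts) + alpha * t_arity
    prob <- if (tot > 0) (counts + alpha) / tot else rep(1 / t_arity, t_arity)
    names(prob) <- t_levels
    list(leaf = TRUE, prob = prob, n = length(idx), counts = counts)
  }

  grow <- function(idx, depth, avail) {
    if (depth >= depth_limit || length(avail) == 0 ||
      length(idx) < min_samples_leaf) {
      return(make_leaf(idx))
    }
    gains <- vapply(
      avail,
      function(v) split_gain(tcode, codes[, v], idx, t_arity, arity[[v]]),
      numeric(1)
    )
    best <- max(gains)
    if (best < min_gain || best <= 0) {
      return(make_leaf(idx))
    }
    # avail is sorted, so the first maximal gain is the lexicographic winner
    var <- avail[which(gains >= best - 1e-12)[1]]
    vcode <- codes[, var]
    children <- lapply(seq_len(arity[[var]]), function(s) {
      grow(idx[vcode[idx] == s], depth + 1L, setdiff(avail, var))
    })
    list(
      leaf = FALSE, var = var, values = data$levels[[var]],
      children = children, n = length(idx)
    )
  }

  node <- grow(seq_len(data$m), 0L, candidates)
  structure(
    list(
      target = target, node = node, levels = t_levels,
      depth_limit = depth_limit, min_gain = min_gain,
      min_samples_leaf = min_samples_leaf, alpha = alpha
    ),
    class = "tree_cpd"
  )
}

#' Parent set of a tree CPD
#'
#' The learned parent set is exactly the set of variables appearing as tests
#' anywhere in the tree.
#'
#' @param tree A `tree_cpd`.
#' @return Sorted character vector of test variable names.
#' @export
tree_parents <- function(tree) {
  stopifnot(inherits(tree, "tree_cpd"))
  collect <- function(node) {
    if (node$leaf) {
      return(character(0))
    }
    c(node$var, unlist(lapply(node$children, collect)))
  }
  sort(unique(collect(tree$node)))
}

# Shallowest depth (1 = root) at which `var` is tested; Inf if absent.
tree_test_depth <- function(tree, var) {
  walk <- function(node, depth) {
    if (node$leaf) {
      return(Inf)
    }
    if (node$var == var) {
      return(depth)
    }
    min(vapply(node$children, walk, numeric(1), depth = depth + 1))
  }
  walk(tree$node, 1)
}

tree_depth <- function(tree) {
  walk <- function(node) {
    if (node$leaf) {
      return(0L)
    }
    1L + max(vapply(node$children, walk, integer(1)))
  }
  walk(tree$node)
}

#' Conditional distribution for one assignment
#'
#' Walks the tree from the root following `assignment` and returns the reached
#' leaf's distribution over the target's states. The assignment may be partial
#' but must cover every test variable on the induced path.
#'
#' @param tree A `tree_cpd`.
#' @param assignment Named character vector (or coercible list) mapping
#'   variable names to state labels.
#' @return Named numeric vector of probabilities summing to one.
#' @export
predict_distribution <- function(tree, assignment = character(0)) {
  stopifnot(inherits(tree, "tree_cpd"))
  assignment <- unlist(assignment)
  node <- tree$node
  while (!node$leaf) {
    if (!node$var %in% names(assignment)) {
      stop(
        "assignment is missing test variable '", node$var,
        "' on the induced path",
        call. = FALSE
      )
    }
    s <- match(as.character(assignment[[node$var]]), node$values)
    if (is.na(s)) {
      stop(
        "unknown state '", assignment[[node$var]], "' for variable '",
        node$var, "'",
        call. = FALSE
      )
    }
    node <- node$children[[s]]
  }
  node$prob
}

#' @export
format.tree_cpd <- function(x, ...) {
  lines <- character(0)
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      lines <<- c(lines, sprintf(
        "%sleaf n=%d: %s", pad, node$n,
        paste(sprintf("P(%s)=%.4f", names(node$prob), node$prob),
          collapse = " "
        )
      ))
    } else {
      for (s in seq_along(node$values)) {
        lines <<- c(lines, sprintf("%s%s = %s:", pad, node$var, node$values[s]))
        walk(node$children[[s]], indent + 1)
      }
    }
  }
  lines <- c(sprintf("tree CPD for %s (depth <= %d)", x$target, x$depth_limit))
  walk(x$node, 1)
  paste(lines, collapse = "\n")
}

#' @export
print.tree_cpd <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
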