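# Independent oracles and fixture generators used across the suite.

# Brute-force plug-in mutual information from a contingency table of counts
# (term-by-term summation, natural log).
oracle_mi <- function(tab) {
  n <- sum(tab)
  out <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        pi_ <- sum(tab[i, ]) / n
        p_j <- sum(tab[, j]) / n
        out <- out + pij * log(pij / (pi_ * p_j))
      }
    }
  }
  out
}

# Dataset with exactly the joint counts of `tab` (rows = states of x).
dataset_from_table <- function(tab) {
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      k <- tab[i, j]
      if (k > 0) {
        rows[[length(rows) + 1]] <-
          data.frame(x = rep(paste0("s", i), k), y = rep(paste0("t", j), k))
      }
    }
  }
  do.call(rbind, rows)
}

# All simple directed cycles of an edge data frame (from, to); returns a list
# of node vectors. Exhaustive DFS, only usable on tiny graphs.
enumerate_cycles <- function(edges, variables) {
  cycles <- list()
  adj <- lapply(variables, function(v) edges$to[edges$from == v])
  names(adj) <- variables
  extend <- function(path) {
    tail <- path[length(path)]
    for (w in adj[[tail]]) {
      if (w == path[1] && length(path) > 1) {
        cycles[[length(cycles) + 1]] <<- path
      } else if (!(w %in% path) && w > path[1]) {
        # only nodes after the anchor, so each cycle is found exactly once,
        # anchored at its smallest node
        extend(c(path, w))
      }
    }
  }
  for (v in variables) extend(v)
  cycles
}

random_digraph <- function(n_nodes, p = 0.3) {
  vars <- LETTERS[seq_len(n_nodes)]
  grid <- expand.grid(from = vars, to = vars, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  keep <- stats::runif(nrow(grid)) < p
  tibble::tibble(from = grid$from[keep], to = grid$to[keep])
}

mixed_from_edges <- function(edges, variables,
                             mark = rep("directed", nrow(edges))) {
  dn2cn:::new_mixed_graph(
    variables,
    tibble::tibble(from = edges$from, to = edges$to, mark = mark)
  )
}

# Independent categorical noise dataset.
random_dataset <- function(n, arities) {
  cols <- lapply(arities, function(k) {
    factor(sample(paste0("s", seq_len(k)), n, replace = TRUE),
      levels = paste0("s", seq_len(k))
    )
  })
  names(cols) <- paste0("v", seq_along(arities))
  tibble::as_tibble(cols)
}

# Random binary ground-truth DAG with strong CPTs (all conditional
# probabilities in {lo, 1 - lo}).
random_truth_network <- function(n_nodes, max_parents = 2, lo = 0.1) {
  vars <- paste0("V", seq_len(n_nodes))
  parents <- stats::setNames(vector("list", n_nodes), vars)
  for (i in seq_len(n_nodes)) {
    pool <- vars[seq_len(i - 1)]
    k <- min(length(pool), sample(0:max_parents, 1))
    parents[[vars[i]]] <- if (k > 0) sort(sample(pool, k)) else character(0)
  }
  cpt <- lapply(parents, function(pa) {
    n_conf <- max(1, 2^length(pa))
    p_yes <- sample(c(lo, 1 - lo), n_conf, replace = TRUE)
    matrix(c(1 - p_yes, p_yes), ncol = 2, dimnames = list(NULL, c("no", "yes")))
  })
  levels <- stats::setNames(rep(list(c("no", "yes")), n_nodes), vars)
  ground_truth_network("random", levels, parents, cpt,
    provenance = "synthetic test fixture"
  )
}

# As random_truth_network, but rejection-sampled so that every parent changes
# its child's conditional in at least one context (without this, rows drawn
# independently can coincide and leave a parent with no effect at all, making
# the edge undetectable in principle).
faithful_truth_network <- function(n_nodes, max_parents = 2, lo = 0.1) {
  vars <- paste0("V", seq_len(n_nodes))
  parents <- stats::setNames(vector("list", n_nodes), vars)
  for (i in seq_len(n_nodes)) {
    pool <- vars[seq_len(i - 1)]
    k <- min(length(pool), sample(0:max_parents, 1))
    parents[[vars[i]]] <- if (k > 0) sort(sample(pool, k)) else character(0)
  }
  cpt <- lapply(parents, function(pa) {
    n_conf <- max(1, 2^length(pa))
    repeat {
      p_yes <- sample(c(lo, 1 - lo), n_conf, replace = TRUE)
      ok <- TRUE
      if (length(pa) >= 1) {
        conf <- as.matrix(expand.grid(rep(list(1:2), length(pa))))
        for (j in seq_along(pa)) {
          other <- conf[, -j, drop = FALSE]
          eff <- FALSE
          for (r in which(conf[, j] == 1)) {
            mate <- which(conf[, j] == 2 &
              apply(other, 1, function(z) all(z == other[r, ])))
            if (p_yes[r] != p_yes[mate]) eff <- TRUE
          }
          if (!eff) ok <- FALSE
        }
      }
      if (ok) break
    }
    matrix(c(1 - p_yes, p_yes), ncol = 2, dimnames = list(NULL, c("no", "yes")))
  })
  levels <- stats::setNames(rep(list(c("no", "yes")), n_nodes), vars)
  ground_truth_network("random", levels, parents, cpt,
    provenance = "synthetic test fixture"
  )
}

expect_edge_sets_equal <- function(got, want) {
  got <- dplyr::arrange(tibble::as_tibble(got[, c("from", "to")]), from, to)
  want <- dplyr::arrange(tibble::as_tibble(want[, c("from", "to")]), from, to)
  expect_equal(as.data.frame(got), as.data.frame(want))
}
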