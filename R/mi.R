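# Pairwise mutual information, edge scoring, and automatic threshold
# selection at the largest adjacent gap of the sorted score list.

#' Plug-in mutual information between two variables
#'
#' The standard plug-in estimator
#' \eqn{\sum_{a,b} \hat p(a,b) \log[\hat p(a,b) / (\hat p(a)\hat p(b))]}
#' over raw empirical frequencies (no smoothing), with the convention
#' \eqn{0 \log(0/\cdot) = 0}. Symmetric and non-negative by construction.
#'
#' @inheritParams learn_tree
#' @param x,y Names of two distinct variables.
#' @param base Logarithm base; the default `exp(1)` reports nats.
#' @return A single non-negative number.
#' @examples
#' d <- data.frame(x = c("0", "0", "1", "1"), y = c("0", "1", "0", "1"))
#' pairwise_mi(d, "x", "y") # exactly factorized: 0
#' @export
pairwise_mi <- function(data, x, y, base = exp(1)) {
  data <- as_discrete_data(data)
  if (x == y) stop("`x` and `y` must be distinct variables", call. = FALSE)
  vars <- variables(data)
  if (!all(c(x, y) %in% vars)) {
    stop("unknown variable(s): ", paste(setdiff(c(x, y), vars), collapse = ", "),
      call. = FALSE
    )
  }
  joint <- table(data$codes[, x], data$codes[, y])
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  ind <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / ind[nz]))
  max(mi, 0) / log(base)
}

#' Score graph adjacencies by mutual information
#'
#' One symmetric MI score per adjacent pair (undirected edges are scored
#' once), returned sorted in descending order. With `all_pairs = TRUE` every
#' variable pair is scored instead of only the graph's adjacencies.
#'
#' @inheritParams pairwise_mi
#' @param graph A `mixed_graph` (or `dependency_network`).
#' @param all_pairs Score every variable pair rather than only adjacent ones.
#' @return A tibble of class `mi_score_table` with columns `x`, `y`
#'   (`x < y`) and `mi`, arranged by decreasing `mi` (ties by name).
#' @export
score_all_edges <- function(data, graph, all_pairs = FALSE, base = exp(1)) {
  data <- as_discrete_data(data)
  if (inherits(graph, "dependency_network")) graph <- collapse_mutual_edges(graph)
  missing_vars <- setdiff(graph$variables, variables(data))
  if (length(missing_vars) > 0) {
    stop("graph variables absent from dataset: ",
      paste(missing_vars, collapse = ", "),
      call. = FALSE
    )
  }
  if (all_pairs) {
    vars <- sort(graph$variables)
    if (length(vars) < 2) {
      pairs <- tibble::tibble(x = character(0), y = character(0))
    } else {
      idx <- utils::combn(vars, 2)
      pairs <- tibble::tibble(x = idx[1, ], y = idx[2, ])
    }
  } else {
    e <- graph$edges
    pairs <- tibble::tibble(x = pmin(e$from, e$to), y = pmax(e$from, e$to))
    pairs <- dplyr::distinct(pairs)
  }
  pairs$mi <- purrr::map2_dbl(pairs$x, pairs$y, function(a, b) {
    pairwise_mi(data, a, b, base = base)
  })
  out <- dplyr::arrange(pairs, dplyr::desc(.data$mi), .data$x, .data$y)
  class(out) <- c("mi_score_table", class(out))
  out
}

mi_lookup <- function(table, from, to) {
  a <- pmin(from, to)
  b <- pmax(from, to)
  idx <- match(paste(a, b, sep = "\r"), paste(table$x, table$y, sep = "\r"))
  if (anyNA(idx)) {
    stop("MI score table does not cover all requested edges", call. = FALSE)
  }
  table$mi[idx]
}

#' Select the MI pruning threshold automatically
#'
#' Scans adjacent pairs of the descending-sorted MI values and finds the pair
#' with the largest absolute difference; the threshold is the smaller value of
#' that pair, so that edges at or below it are prunable. Ties on the gap are
#' broken by the first (highest-MI) occurrence. A single-entry table yields a
#' threshold of zero (nothing auto-prunable).
#'
#' @param table A [score_all_edges()] result (or any tibble with an `mi`
#'   column), non-empty.
#' @return A `delta_threshold`: a number with a `provenance` attribute
#'   (`"auto"`).
#' @examples
#' tab <- tibble::tibble(
#'   x = c("a", "a", "b", "c"), y = c("b", "c", "d", "d"),
#'   mi = c(0.90, 0.85, 0.30, 0.28)
#' )
#' select_delta(tab) # largest gap 0.85 -> 0.30, so delta = 0.30
#' @export
select_delta <- function(table) {
  if (nrow(table) == 0) {
    stop("cannot select a threshold from an empty MI table", call. = FALSE)
  }
  mi <- sort(table$mi, decreasing = TRUE)
  if (length(mi) == 1) {
    return(new_delta(0, "auto"))
  }
  gaps <- abs(diff(mi))
  i <- which.max(gaps) # first occurrence on ties
  new_delta(mi[i + 1], "auto")
}

new_delta <- function(value, provenance) {
  stopifnot(value >= 0, provenance %in% c("auto", "user"))
  structure(value, provenance = provenance, class = "delta_threshold")
}

#' @export
print.delta_threshold <- function(x, ...) {
  cat(sprintf(
    "<delta_threshold> %.6g nats (%s)\n",
    unclass(x), attr(x, "provenance")
  ))
  invisible(x)
}
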