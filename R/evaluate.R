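# Orientation-sensitive structure-recovery metrics and the benchmark
# harness.

as_edge_set <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("from", "to") %in% names(x)))
    return(tibble::as_tibble(x[, c("from", "to")]))
  }
  if (inherits(x, "ground_truth_network")) {
    return(network_edges(x))
  }
  if (inherits(x, "causal_network")) {
    return(x$edges)
  }
  if (inherits(x, "mixed_graph")) {
    if (nrow(undirected_edges(x)) > 0) {
      stop("graph still contains undirected edges", call. = FALSE)
    }
    return(directed_edges(x))
  }
  if (inherits(x, "dependency_network")) {
    return(x$edges)
  }
  stop("cannot interpret object as an edge set", call. = FALSE)
}

graph_variables <- function(x) {
  if (is.data.frame(x)) {
    return(NULL)
  }
  x$variables
}

#' Structure-recovery metrics against a ground truth
#'
#' An arc is counted correct only when the same arc exists in the ground
#' truth with the same orientation. A reversed arc therefore counts both as a
#' false edge (wrong orientation) and as a missed true arc. The metrics are
#' the true edge rate (correct / number of truth arcs), the false edge count
#' (learned arcs that are not correct, an absolute count), and the missed
#' edge rate (truth arcs not matched / number of truth arcs);
#' `true_edge_rate + missed_edge_rate = 1`.
#'
#' @param learned Learned DAG: a `causal_network`, `mixed_graph` without
#'   undirected edges, or an edge tibble with columns `from`, `to`.
#' @param truth Ground-truth DAG in any of the same forms (or a
#'   `ground_truth_network`).
#' @param skeleton If `TRUE`, compare unordered adjacencies instead
#'   (orientation-insensitive diagnostic).
#' @return A one-row tibble with columns `true_edge_rate`,
#'   `false_edge_count`, `missed_edge_rate`, `n_correct`, `n_learned`,
#'   `n_truth`.
#' @export
evaluate_structure <- function(learned, truth, skeleton = FALSE) {
  le <- as_edge_set(learned)
  te <- as_edge_set(truth)
  lv <- graph_variables(learned)
  tv <- graph_variables(truth)
  if (!is.null(lv) && !is.null(tv) && !setequal(lv, tv)) {
    stop("learned and truth graphs are over different variable sets",
      call. = FALSE
    )
  }
  if (skeleton) {
    le <- dplyr::distinct(tibble::tibble(
      from = pmin(le$from, le$to), to = pmax(le$from, le$to)
    ))
    te <- dplyr::distinct(tibble::tibble(
      from = pmin(te$from, te$to), to = pmax(te$from, te$to)
    ))
  }
  lkey <- paste(le$from, le$to, sep = "\r")
  tkey <- paste(te$from, te$to, sep = "\r")
  correct <- sum(lkey %in% tkey)
  n_truth <- length(tkey)
  tibble::tibble(
    true_edge_rate = if (n_truth > 0) correct / n_truth else NA_real_,
    false_edge_count = length(lkey) - correct,
    missed_edge_rate = if (n_truth > 0) (n_truth - correct) / n_truth else NA_real_,
    n_correct = correct,
    n_learned = length(lkey),
    n_truth = n_truth
  )
}

#' Run a structure-recovery benchmark
#'
#' Forward-samples `n` rows from a bundled ground-truth network (or uses a
#' supplied dataset), runs the full [dn2cn()] pipeline, evaluates the learned
#' DAG against the truth, and scores the joint log-likelihood of both the
#' learned and the truth network on the same data.
#'
#' @inheritParams bundled_network
#' @inheritParams dn2cn
#' @param n Number of samples to draw (ignored when `data` is given).
#' @param seed Integer seed for the forward sampler.
#' @param depth Structure-phase tree depth limit.
#' @param data Optional dataset (data frame) for exact reproduction instead
#'   of sampling.
#' @param ... Further arguments passed to [dn2cn()].
#' @return A list of class `benchmark_result` with fields `name`, `metrics`,
#'   `loglik_learned`, `loglik_truth`, `fit`, `truth`, `n`; `tidy()` returns
#'   a one-row tibble.
#' @export
run_benchmark <- function(name, n = 10000, seed = NULL, delta = "auto",
                          depth = 2, data = NULL, ...) {
  truth <- bundled_network(name)
  if (is.null(data)) {
    data <- forward_sample(truth, n, seed = seed)
  }
  data <- as_discrete_data(data)
  fit <- dn2cn(data, delta = delta, depth_limit = depth, ...)
  metrics <- evaluate_structure(fit, truth)
  structure(
    list(
      name = truth$name,
      metrics = metrics,
      loglik_learned = log_likelihood(data, fit),
      loglik_truth = log_likelihood(data, truth),
      fit = fit,
      truth = truth,
      n = data$m
    ),
    class = "benchmark_result"
  )
}

#' @export
tidy.benchmark_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(name = x$name, n = x$n),
    x$metrics,
    tibble::tibble(
      loglik_learned = x$loglik_learned,
      loglik_truth = x$loglik_truth,
      delta = x$fit$report$delta
    )
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s (n = %d)\n", x$name, x$n))
  m <- x$metrics
  cat(sprintf(
    "  true edge rate %.3f | false edges %d | missed edge rate %.3f\n",
    m$true_edge_rate, m$false_edge_count, m$missed_edge_rate
  ))
  cat(sprintf(
    "  log-likelihood: learned %.2f, truth %.2f\n",
    x$loglik_learned, x$loglik_truth
  ))
  invisible(x)
}
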