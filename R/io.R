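# Graph serialization: edge-list TSV (canonical interchange format) and DOT
# (presentation only). Output is byte-stable for a fixed graph.

graph_rows <- function(graph, table = NULL) {
  edges <- if (is.data.frame(graph)) {
    e <- tibble::as_tibble(graph)
    if (!"mark" %in% names(e)) e$mark <- "directed"
    e[, c("from", "to", "mark")]
  } else if (inherits(graph, "mixed_graph")) {
    graph$edges
  } else {
    e <- as_edge_set(graph)
    new_edge_tibble(e$from, e$to, rep("directed", nrow(e)))
  }
  out <- tibble::tibble(
    source = edges$from, target = edges$to, mark = edges$mark
  )
  out$mi_score <- if (!is.null(table) && nrow(out) > 0) {
    mi_lookup(table, out$source, out$target)
  } else {
    rep(NA_real_, nrow(out))
  }
  dplyr::arrange(out, .data$source, .data$target)
}

#' Write a graph to disk
#'
#' The edge-list TSV (columns `source`, `target`, `mark`, `mi_score`, edges
#' sorted lexicographically by source then target) is the canonical
#' interchange format; DOT output is for presentation and renders undirected
#' edges without arrowheads. Serialization is deterministic: identical graphs
#' produce identical bytes.
#'
#' @param graph A `mixed_graph`, `causal_network`, `ground_truth_network`,
#'   `dependency_network`, or an edge data frame with columns `from`, `to`
#'   (and optionally `mark`).
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"dot"`.
#' @param table Optional [score_all_edges()] table supplying `mi_score`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("tsv", "dot"), table = NULL) {
  format <- match.arg(format)
  rows <- graph_rows(graph, table)
  if (format == "tsv") {
    readr::write_tsv(rows, path, progress = FALSE)
  } else {
    lines <- c("digraph G {")
    if (nrow(rows) > 0) {
      style <- ifelse(rows$mark == "undirected", " [dir=none]", "")
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\"%s;", rows$source, rows$target, style
      ))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an edge-list TSV
#'
#' @param path A file written by [write_graph()] (or any TSV with columns
#'   `source`, `target` and optionally `mark`, `mi_score`).
#' @return A tibble with columns `from`, `to`, `mark` (and `mi` when
#'   present).
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      source = readr::col_character(),
      target = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  out <- tibble::tibble(
    from = df$source,
    to = df$target,
    mark = if ("mark" %in% names(df)) df$mark else rep("directed", nrow(df))
  )
  if ("mi_score" %in% names(df)) out$mi <- df$mi_score
  out
}
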