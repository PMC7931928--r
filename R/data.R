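#' Discrete datasets
#'
#' A discrete dataset is a rectangular table of fully observed categorical
#' variables: rows are samples, columns are variables. Internally every column
#' is encoded as dense integer codes `1..arity`; for character and numeric
#' input the code order is the order in which states first appear in the
#' column, so that downstream results (information gains, mutual information,
#' tree structure) are reproducible across runs for the same file. Columns
#' that are already factors keep their declared level order.
#'
#' @param x A data frame (or tibble) of categorical columns, or an object
#'   already of class `discrete_data`.
#' @return An object of class `discrete_data`: a list with elements `tbl`
#'   (tibble of factors), `codes` (integer matrix, 1-based codes), `levels`
#'   (named list of state labels per variable), `arity` (named integer vector),
#'   `m` (number of samples) and `n` (number of variables).
#' @examples
#' d <- as_discrete_data(data.frame(x = c("a", "b", "a"), y = c(1, 1, 2)))
#' d$arity
#' @export
as_discrete_data <- function(x) {
  if (inherits(x, "discrete_data")) {
    return(x)
  }
  if (!is.data.frame(x)) {
    stop("`x` must be a data frame of categorical columns", call. = FALSE)
  }
  if (ncol(x) < 1) {
    stop("dataset has no columns", call. = FALSE)
  }
  nms <- names(x)
  if (anyDuplicated(nms)) {
    stop("variable names must be unique", call. = FALSE)
  }
  for (j in seq_along(x)) {
    col <- x[[j]]
    bad <- which(is.na(col) | (if (is.character(col)) !nzchar(col) else FALSE))
    if (length(bad) > 0) {
      stop(sprintf(
        "missing value in column '%s', row %d: datasets must be fully observed",
        nms[j], bad[1]
      ), call. = FALSE)
    }
  }
  cols <- lapply(seq_along(x), function(j) {
    col <- x[[j]]
    if (is.factor(col)) {
      factor(col, levels = levels(col))
    } else {
      col <- as.character(col)
      factor(col, levels = unique(col))
    }
  })
  names(cols) <- nms
  arity <- vapply(cols, nlevels, integer(1))
  const <- nms[arity < 2]
  if (length(const) > 0) {
    warning(
      "constant column(s) retained (arity 1): ",
      paste(const, collapse = ", "),
      call. = FALSE
    )
  }
  codes <- vapply(cols, as.integer, integer(nrow(x)))
  if (nrow(x) == 1L) codes <- matrix(codes, nrow = 1, dimnames = list(NULL, nms))
  structure(
    list(
      tbl = tibble::as_tibble(cols),
      codes = codes,
      levels = lapply(cols, levels),
      arity = arity,
      m = nrow(x),
      n = length(cols)
    ),
    class = "discrete_data"
  )
}

#' @export
print.discrete_data <- function(x, ...) {
  cat(sprintf(
    "<discrete_data> %d samples x %d variables\n", x$m, x$n
  ))
  cat("arities: ", paste(sprintf("%s(%d)", names(x$arity), x$arity),
    collapse = ", "
  ), "\n", sep = "")
  invisible(x)
}

#' @export
dim.discrete_data <- function(x) c(x$m, x$n)

#' @rdname as_discrete_data
#' @export
variables <- function(x) {
  names(as_discrete_data(x)$arity)
}

#' Read and write discrete datasets
#'
#' `read_discrete()` reads a delimited text file (comma or tab separated, with
#' a header row) into a [as_discrete_data()] object. All cells are read as
#' text; state labels are mapped to dense integer codes per column in
#' first-appearance order and the mapping is retained so a written file
#' round-trips exactly. `write_discrete()` writes the original labels back
#' out.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter. `NULL` (default) auto-detects comma versus
#'   tab from the header line; anything else must be passed explicitly.
#' @return `read_discrete()` returns a `discrete_data`; `write_discrete()`
#'   returns `path` invisibly.
#' @export
read_discrete <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    show_col_types = FALSE
  )
  if (nrow(df) == 0) {
    stop("dataset has no rows: ", path, call. = FALSE)
  }
  as_discrete_data(as.data.frame(df, check.names = FALSE))
}

#' @param data A data frame or `discrete_data`.
#' @rdname read_discrete
#' @export
write_discrete <- function(data, path, delim = ",") {
  data <- as_discrete_data(data)
  out <- data$tbl
  out[] <- lapply(out, as.character)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read a variable ordering file
#'
#' One variable name per line; earlier lines are allowed ancestors of later
#' ones. The ordering may cover only a subset of the dataset's variables.
#'
#' @param path Path to a plain-text file, one name per line.
#' @return Character vector of variable names.
#' @export
read_ordering <- function(path) {
  ord <- readLines(path, warn = FALSE)
  ord <- trimws(ord)
  ord <- ord[nzchar(ord)]
  if (anyDuplicated(ord)) {
    stop("ordering contains duplicated names", call. = FALSE)
  }
  ord
}

# Validate an ordering against a dataset; returns the ordering invisibly.
check_ordering <- function(ordering, data) {
  if (is.null(ordering)) {
    return(invisible(NULL))
  }
  unknown <- setdiff(ordering, variables(data))
  if (length(unknown) > 0) {
    stop(
      "ordering names unknown variable(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(ordering)
}
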