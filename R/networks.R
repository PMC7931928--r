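# Ground-truth networks with explicit table CPDs: constructor, validation,
# and the bundled benchmark fixtures.

#' Construct a ground-truth network with table CPDs
#'
#' @param name Network name.
#' @param levels Named list: state labels per variable.
#' @param parents Named list: character vector of parent names per variable
#'   (empty for roots). The graph must be acyclic.
#' @param cpt Named list of probability matrices, one per variable, with one
#'   row per parent configuration (first parent varying fastest, matching
#'   `expand.grid()` order) and one column per state; rows must sum to one.
#' @param provenance Free-text provenance note.
#' @return An object of class `ground_truth_network`.
#' @export
ground_truth_network <- function(name, levels, parents, cpt, provenance = "") {
  vars <- names(levels)
  stopifnot(
    setequal(vars, names(parents)),
    setequal(vars, names(cpt))
  )
  arity <- vapply(levels, length, integer(1))
  edges <- parents_to_edges(parents)
  if (!edges_acyclic(edges, vars)) {
    stop("ground-truth network must be acyclic", call. = FALSE)
  }
  for (v in vars) {
    p <- cpt[[v]]
    n_conf <- prod(arity[parents[[v]]])
    if (length(parents[[v]]) == 0) n_conf <- 1
    if (!is.matrix(p) || nrow(p) != n_conf || ncol(p) != arity[[v]]) {
      stop(sprintf(
        "CPT for '%s' must be %d configurations x %d states", v, n_conf,
        arity[[v]]
      ), call. = FALSE)
    }
    if (any(abs(rowSums(p) - 1) > 1e-9) || any(p < 0)) {
      stop("CPT rows for '", v, "' must be non-negative and sum to 1",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      name = name, variables = vars, levels = levels, parents = parents,
      cpt = cpt, provenance = provenance
    ),
    class = "ground_truth_network"
  )
}

parents_to_edges <- function(parents) {
  purrr::map_dfr(names(parents), function(v) {
    pa <- parents[[v]]
    if (length(pa) == 0) {
      return(tibble::tibble(from = character(0), to = character(0)))
    }
    tibble::tibble(from = pa, to = v)
  })
}

#' Edge list of a network
#'
#' @param net A `ground_truth_network` or `causal_network`.
#' @return Tibble with columns `from`, `to`, sorted lexicographically.
#' @export
network_edges <- function(net) {
  edges <- if (inherits(net, "ground_truth_network")) {
    parents_to_edges(net$parents)
  } else {
    dag_edges(net)
  }
  dplyr::arrange(edges, .data$from, .data$to)
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_network> '%s': %d variables, %d edges\n",
    x$name, length(x$variables), nrow(network_edges(x))
  ))
  if (nzchar(x$provenance)) cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ground_truth_network <- function(x, ...) {
  network_edges(x)
}

cpd_config_matrix <- function(net, v) {
  net$cpt[[v]]
}

# Row index into the CPT of `v` for every sample, given sampled parent codes
# (first parent varies fastest).
config_index <- function(net, v, codes) {
  pa <- net$parents[[v]]
  if (length(pa) == 0) {
    return(rep(1L, nrow(codes)))
  }
  arity <- vapply(net$levels[pa], length, integer(1))
  idx <- rep(1L, nrow(codes))
  stride <- 1L
  for (j in seq_along(pa)) {
    idx <- idx + (codes[, pa[j]] - 1L) * stride
    stride <- stride * arity[j]
  }
  idx
}

# P(observed state | observed parent config) for every row of `data`.
cpd_row_probs <- function(net, v, data) {
  recode <- function(w) {
    match(data$levels[[w]], net$levels[[w]])[data$codes[, w]]
  }
  vars_needed <- c(v, net$parents[[v]])
  codes <- vapply(vars_needed, recode, integer(data$m))
  if (data$m == 1L) {
    codes <- matrix(codes, nrow = 1, dimnames = list(NULL, vars_needed))
  } else {
    colnames(codes) <- vars_needed
  }
  idx <- config_index(net, v, codes)
  net$cpt[[v]][cbind(idx, codes[, v])]
}

binary_cpt <- function(p_yes) {
  matrix(c(1 - p_yes, p_yes), ncol = 2,
    dimnames = list(NULL, c("no", "yes"))
  )
}

#' Bundled ground-truth benchmark networks
#'
#' Returns one of the networks used throughout the package's tests and
#' examples:
#'
#' * `"asia"` — the classic eight-node binary chest-clinic network with its
#'   published conditional probability tables (visit to Asia, tuberculosis,
#'   smoking, lung cancer, bronchitis, tuberculosis-or-cancer, X-ray,
#'   dyspnoea).
#' * `"lucas"` — the twelve-node binary lung-cancer diagnosis network; the
#'   structure is the published one, the CPT values are synthetic stand-ins
#'   of comparable strength (the published generative tables are not
#'   redistributed here).
#' * `"sachs"` — the eleven-node protein-signalling consensus network
#'   (3 states per node, 18 directed interactions); CPTs are synthetic
#'   stand-ins, as the real data are experimental measurements.
#' * `"demo6"` — a six-variable binary demonstration network used by the
#'   worked example (final DAG `B->A, C->B, D->B, B->E, F->E`), with
#'   synthetic CPTs.
#'
#' @param name One of `"lucas"`, `"asia"`, `"sachs"`, `"demo6"`.
#' @return A [ground_truth_network()].
#' @export
bundled_network <- function(name = c("lucas", "asia", "sachs", "demo6")) {
  name <- match.arg(name)
  switch(name,
    asia = asia_network(),
    lucas = lucas_network(),
    sachs = sachs_network(),
    demo6 = demo6_network()
  )
}

asia_network <- function() {
  vars <- c("asia", "tub", "smoke", "lung", "bronc", "either", "xray", "dysp")
  levels <- stats::setNames(rep(list(c("no", "yes")), length(vars)), vars)
  parents <- list(
    asia = character(0),
    tub = "asia",
    smoke = character(0),
    lung = "smoke",
    bronc = "smoke",
    either = c("lung", "tub"),
    xray = "either",
    dysp = c("bronc", "either")
  )
  cpt <- list(
    asia = binary_cpt(0.01),
    tub = binary_cpt(c(0.01, 0.05)), # asia = no, yes
    smoke = binary_cpt(0.5),
    lung = binary_cpt(c(0.01, 0.10)), # smoke = no, yes
    bronc = binary_cpt(c(0.30, 0.60)),
    # lung fastest: (no,no), (yes,no), (no,yes), (yes,yes) -- logical OR
    either = binary_cpt(c(0, 1, 1, 1)),
    xray = binary_cpt(c(0.05, 0.98)),
    # bronc fastest: (no,no), (yes,no), (no,yes), (yes,yes)
    dysp = binary_cpt(c(0.10, 0.80, 0.70, 0.90))
  )
  ground_truth_network(
    "asia", levels, parents, cpt,
    provenance = "chest-clinic network with its published generative CPTs"
  )
}

lucas_network <- function() {
  vars <- c(
    "anxiety", "peer_pressure", "smoking", "yellow_fingers", "genetics",
    "lung_cancer", "attention_disorder", "allergy", "coughing", "fatigue",
    "car_accident", "born_even_day"
  )
  levels <- stats::setNames(rep(list(c("no", "yes")), length(vars)), vars)
  parents <- list(
    anxiety = character(0),
    peer_pressure = character(0),
    smoking = c("anxiety", "peer_pressure"),
    yellow_fingers = "smoking",
    genetics = character(0),
    lung_cancer = c("genetics", "smoking"),
    attention_disorder = "genetics",
    allergy = character(0),
    coughing = c("allergy", "lung_cancer"),
    fatigue = c("lung_cancer", "coughing"),
    car_accident = c("attention_disorder", "fatigue"),
    born_even_day = character(0)
  )
  cpt <- list(
    anxiety = binary_cpt(0.64),
    peer_pressure = binary_cpt(0.33),
    smoking = binary_cpt(c(0.42, 0.86, 0.71, 0.92)), # anxiety fastest
    yellow_fingers = binary_cpt(c(0.23, 0.95)),
    genetics = binary_cpt(0.16),
    lung_cancer = binary_cpt(c(0.21, 0.82, 0.85, 0.99)), # genetics fastest
    attention_disorder = binary_cpt(c(0.28, 0.67)),
    allergy = binary_cpt(0.33),
    coughing = binary_cpt(c(0.17, 0.65, 0.82, 0.92)), # allergy fastest
    fatigue = binary_cpt(c(0.12, 0.68, 0.62, 0.92)), # lung_cancer fastest
    car_accident = binary_cpt(c(0.10, 0.72, 0.68, 0.95)), # att. dis. fastest
    born_even_day = binary_cpt(0.5)
  )
  ground_truth_network(
    "lucas", levels, parents, cpt,
    provenance = paste(
      "published 12-node lung-cancer diagnosis structure;",
      "CPT values are synthetic stand-ins of comparable strength"
    )
  )
}

sachs_network <- function() {
  vars <- c(
    "Akt", "Erk", "Jnk", "Mek", "P38", "PIP2", "PIP3", "PKA", "PKC",
    "Plcg", "Raf"
  )
  levels <- stats::setNames(rep(list(c("low", "med", "high")), length(vars)), vars)
  parents <- list(
    Akt = c("Erk", "PKA", "PIP3"),
    Erk = c("Mek", "PKA"),
    Jnk = c("PKA", "PKC"),
    Mek = c("PKA", "PKC", "Raf"),
    P38 = c("PKA", "PKC"),
    PIP2 = c("PIP3", "Plcg"),
    PIP3 = "Plcg",
    PKA = "PKC",
    PKC = character(0),
    Plcg = character(0),
    Raf = c("PKA", "PKC")
  )
  # synthetic 3-state CPTs: the child's level follows the mean of its parent
  # levels with Gaussian-kernel noise (deterministic construction)
  kernel_cpt <- function(n_parents) {
    if (n_parents == 0) {
      return(matrix(c(0.4, 0.35, 0.25), nrow = 1,
        dimnames = list(NULL, c("low", "med", "high"))
      ))
    }
    configs <- as.matrix(expand.grid(rep(list(1:3), n_parents)))
    rows <- t(apply(configs, 1, function(conf) {
      mu <- mean(conf)
      w <- exp(-1.4 * (1:3 - mu)^2)
      w / sum(w)
    }))
    colnames(rows) <- c("low", "med", "high")
    rows
  }
  cpt <- lapply(parents, function(pa) kernel_cpt(length(pa)))
  ground_truth_network(
    "sachs", levels, parents, cpt,
    provenance = paste(
      "11-node protein-signalling consensus structure (18 interactions);",
      "CPTs are synthetic stand-ins"
    )
  )
}

demo6_network <- function() {
  vars <- c("A", "B", "C", "D", "E", "F")
  levels <- stats::setNames(rep(list(c("0", "1")), length(vars)), vars)
  binary01 <- function(p_yes) {
    matrix(c(1 - p_yes, p_yes), ncol = 2, dimnames = list(NULL, c("0", "1")))
  }
  parents <- list(
    A = "B",
    B = c("C", "D"),
    C = character(0),
    D = character(0),
    E = c("B", "F"),
    F = character(0)
  )
  cpt <- list(
    A = binary01(c(0.15, 0.90)), # B = 0, 1
    B = binary01(c(0.10, 0.80, 0.75, 0.95)), # C fastest
    C = binary01(0.5),
    D = binary01(0.5),
    E = binary01(c(0.05, 0.75, 0.70, 0.95)), # B fastest
    F = binary01(0.5)
  )
  ground_truth_network(
    "demo6", levels, parents, cpt,
    provenance = "six-variable synthetic demonstration network"
  )
}
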