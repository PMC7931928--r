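test_that("a fully directed graph passes through orientation unchanged", {
  fx <- demo_network_fixture()
  dag <- mixed_from_edges(
    tibble::tibble(from = c("A", "B"), to = c("B", "C")), c("A", "B", "C")
  )
  tab <- tibble::tibble(x = c("A", "B"), y = c("B", "C"), mi = c(0.3, 0.2))
  out <- orient_edges(dag, tab)
  expect_equal(out$edges, dag$edges)
  expect_equal(nrow(attr(out, "orientations")), 0)
})

test_that("acyclicity forces the only legal direction", {
  # directed path A -> B -> C plus undirected A -- C: C -> A would close a
  # cycle, so A -> C is forced
  g <- dn2cn:::new_mixed_graph(
    c("A", "B", "C"),
    tibble::tibble(
      from = c("A", "B", "A"), to = c("B", "C", "C"),
      mark = c("directed", "directed", "undirected")
    )
  )
  tab <- tibble::tibble(
    x = c("A", "B", "A"), y = c("B", "C", "C"), mi = c(0.5, 0.4, 0.3)
  )
  out <- orient_edges(g, tab)
  o <- attr(out, "orientations")
  expect_equal(o$reason, "acyclicity")
  expect_equal(paste(o$from, o$to), "A C")
})

test_that("tree-depth evidence orients toward the shallower tester", {
  df <- data.frame(
    p = rep(c("0", "1"), each = 50),
    q = rep(c("0", "1"), each = 50)
  )
  # p's tree tests q at depth 1; q's tree is built to test p at depth 2
  deep_tree <- function(target, other1, other2) {
    dn2cn:::manual_tree(target, dn2cn:::manual_split(other1, list(
      dn2cn:::manual_split(other2, list(
        dn2cn:::manual_leaf(0.2, 25), dn2cn:::manual_leaf(0.8, 25)
      ), 50),
      dn2cn:::manual_leaf(0.9, 50)
    ), 100))
  }
  shallow_tree <- function(target, other) {
    dn2cn:::manual_tree(target, dn2cn:::manual_split(other, list(
      dn2cn:::manual_leaf(0.1, 50), dn2cn:::manual_leaf(0.9, 50)
    ), 100))
  }
  dn <- structure(
    list(
      variables = c("p", "q", "r"),
      edges = tibble::tibble(from = c("q", "p", "r"), to = c("p", "q", "q")),
      trees = list(
        p = shallow_tree("p", "q"),
        q = deep_tree("q", "r", "p"),
        r = shallow_tree("r", "q")
      )
    ),
    class = "dependency_network"
  )
  g <- dn2cn:::new_mixed_graph(
    c("p", "q", "r"),
    tibble::tibble(from = "p", to = "q", mark = "undirected")
  )
  tab <- tibble::tibble(x = "p", y = "q", mi = 0.2)
  out <- orient_edges(g, tab, dn)
  o <- attr(out, "orientations")
  expect_equal(o$reason, "tree_depth")
  # p tests q at depth 1 < q tests p at depth 2, so p is upstream
  expect_equal(paste(o$from, o$to), "p q")
})

test_that("lexicographic ties orient from the later name to the earlier", {
  g <- dn2cn:::new_mixed_graph(
    c("a", "b"),
    tibble::tibble(from = "a", to = "b", mark = "undirected")
  )
  tab <- tibble::tibble(x = "a", y = "b", mi = 0.1)
  out <- orient_edges(g, tab)
  o <- attr(out, "orientations")
  expect_equal(o$reason, "lexicographic")
  expect_equal(paste(o$from, o$to), "b a")
})

test_that("an undirected triangle becomes one of the acyclic orientations", {
  g <- dn2cn:::new_mixed_graph(
    c("A", "B", "C"),
    tibble::tibble(
      from = c("A", "A", "B"), to = c("B", "C", "C"),
      mark = rep("undirected", 3)
    )
  )
  tab <- tibble::tibble(
    x = c("A", "A", "B"), y = c("B", "C", "C"), mi = c(0.3, 0.2, 0.1)
  )
  out <- orient_edges(g, tab)
  expect_equal(nrow(dn2cn:::undirected_edges(out)), 0)
  e <- dn2cn:::directed_edges(out)
  expect_equal(nrow(e), 3)
  # topological-sort oracle confirms acyclicity
  ig <- igraph::graph_from_data_frame(e, directed = TRUE)
  expect_true(igraph::is_dag(ig))
})

test_that("the fixture's undirected pairs are oriented as D -> B and F -> E", {
  fx <- demo_network_fixture()
  mg <- collapse_mutual_edges(fx$dn)
  pruned <- break_cycles(mg, fx$mi, select_delta(fx$mi))
  out <- orient_edges(pruned, fx$mi, fx$dn)
  o <- attr(out, "orientations")
  # processed in descending MI order: E--F first, then B--D
  expect_equal(paste(o$from, o$to), c("F E", "D B"))
})
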