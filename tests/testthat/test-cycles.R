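test_that("the fixture's shortest cycle is found", {
  fx <- demo_network_fixture()
  mg <- collapse_mutual_edges(fx$dn)
  expect_equal(find_shortest_cycle(mg), c("A", "C", "B"))
})

test_that("acyclic graphs report no cycle", {
  dag <- mixed_from_edges(
    tibble::tibble(from = c("A", "B", "A"), to = c("B", "C", "C")),
    c("A", "B", "C")
  )
  expect_null(find_shortest_cycle(dag))
  empty <- mixed_from_edges(
    tibble::tibble(from = character(0), to = character(0)), c("A", "B"),
    mark = character(0)
  )
  expect_null(find_shortest_cycle(empty))
})

test_that("shortest-cycle length matches exhaustive enumeration", {
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(3:7, 1)
      edges <- random_digraph(n, p = stats::runif(1, 0.15, 0.5))
      vars <- LETTERS[seq_len(n)]
      g <- mixed_from_edges(edges, vars)
      got <- find_shortest_cycle(g)
      all_cycles <- enumerate_cycles(edges, vars)
      if (length(all_cycles) == 0) {
        expect_null(got)
      } else {
        min_len <- min(lengths(all_cycles))
        expect_equal(length(got), min_len)
        # and the returned sequence really is a cycle of the graph
        key <- paste(edges$from, edges$to)
        steps <- paste(got, c(got[-1], got[1]))
        expect_true(all(steps %in% key))
      }
    }
  })
})

test_that("cycle breaking removes weak edges and always terminates acyclic", {
  fx <- demo_network_fixture()
  mg <- collapse_mutual_edges(fx$dn)
  pruned <- break_cycles(mg, fx$mi, select_delta(fx$mi))
  rem <- attr(pruned, "removals")
  expect_equal(rem$from, "A")
  expect_equal(rem$to, "C")
  expect_equal(rem$rule, "below_delta")
  expect_null(find_shortest_cycle(pruned))
  # an acyclic graph passes through unchanged
  again <- break_cycles(pruned, fx$mi, select_delta(fx$mi))
  expect_equal(again$edges, pruned$edges)
  expect_equal(nrow(attr(again, "removals")), 0)
})

test_that("the fallback deletes the cycle's weakest edge when none is below delta", {
  edges <- tibble::tibble(from = c("A", "B", "C"), to = c("B", "C", "A"))
  g <- mixed_from_edges(edges, c("A", "B", "C"))
  tab <- tibble::tibble(
    x = c("A", "B", "A"), y = c("B", "C", "C"), mi = c(0.5, 0.4, 0.3)
  )
  pruned <- break_cycles(g, tab, 0.1)
  rem <- attr(pruned, "removals")
  expect_equal(rem$rule, "fallback_min")
  expect_equal(paste(rem$from, rem$to), "C A") # pair (A, C) has the lowest MI
  expect_null(find_shortest_cycle(pruned))
  expect_equal(nrow(pruned$edges), 2)
})

test_that("deletions match an independent simulation of the same rule", {
  # independent re-implementation: shortest cycle via exhaustive enumeration
  # (smallest canonical rotation), same deletion policy
  oracle_break <- function(edges, vars, tab, delta) {
    mi_of <- function(f, t) {
      a <- pmin(f, t)
      b <- pmax(f, t)
      tab$mi[match(paste(a, b), paste(tab$x, tab$y))]
    }
    repeat {
      cycles <- enumerate_cycles(edges, vars)
      if (length(cycles) == 0) {
        return(dplyr::arrange(edges, from, to))
      }
      lens <- lengths(cycles)
      shortest <- cycles[lens == min(lens)]
      keys <- vapply(shortest, paste, "", collapse = "\r")
      cyc <- shortest[[order(keys)[1]]]
      ce <- tibble::tibble(from = cyc, to = c(cyc[-1], cyc[1]))
      ce$mi <- mi_of(ce$from, ce$to)
      drop <- which(ce$mi <= delta)
      if (length(drop) == 0) {
        drop <- order(ce$mi, ce$from, ce$to)[1]
      }
      rm_key <- paste(ce$from[drop], ce$to[drop])
      edges <- edges[!(paste(edges$from, edges$to) %in% rm_key), ]
    }
  }
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(4:6, 1)
      vars <- LETTERS[seq_len(n)]
      edges <- random_digraph(n, p = 0.4)
      pairs <- unique(tibble::tibble(
        x = pmin(edges$from, edges$to), y = pmax(edges$from, edges$to)
      ))
      pairs$mi <- round(stats::runif(nrow(pairs), 0, 0.5), 3)
      delta <- round(stats::runif(1, 0, 0.3), 3)
      got <- break_cycles(mixed_from_edges(edges, vars), pairs, delta)
      want <- oracle_break(edges, vars, pairs, delta)
      expect_equal(
        as.data.frame(dplyr::arrange(got$edges[, c("from", "to")], from, to)),
        as.data.frame(want)
      )
    }
  })
})
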