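and_dataset <- function(reps = 100) {
  grid <- expand.grid(
    x1 = c("0", "1"), x2 = c("0", "1"),
    stringsAsFactors = FALSE
  )
  df <- grid[rep(seq_len(nrow(grid)), each = reps), ]
  df$y <- ifelse(df$x1 == "1" & df$x2 == "1", "1", "0")
  df
}

# exactly factorized: every (x1, x2, y) combination equally frequent
factorized_dataset <- function(reps = 5) {
  grid <- expand.grid(
    x1 = c("0", "1"), x2 = c("0", "1"), y = c("0", "1"),
    stringsAsFactors = FALSE
  )
  grid[rep(seq_len(nrow(grid)), each = reps), ]
}

test_that("a conjunction is learned as a two-test tree with both parents", {
  df <- and_dataset(100)
  tree <- learn_tree(df, "y", c("x1", "x2"), depth_limit = 2)
  expect_setequal(tree_parents(tree), c("x1", "x2"))
  # exhaustive gain computation on the 4-cell table: both orders are valid,
  # and the lexicographic tie-break makes x1 the root
  expect_equal(tree$node$var, "x1")
  p <- predict_distribution(tree, c(x1 = "1", x2 = "1"))
  expect_equal(sum(p), 1)
  expect_equal(unname(p["1"]), 101 / 102) # 100 counts + alpha = 1 smoothing
  p0 <- predict_distribution(tree, c(x1 = "0", x2 = "0"))
  expect_lt(p0[["1"]], 0.02)
})

test_that("an exactly independent target yields a single leaf", {
  df <- factorized_dataset()
  tree <- learn_tree(df, "y", c("x1", "x2"), min_gain = 1e-6)
  expect_equal(tree_parents(tree), character(0))
  expect_true(tree$node$leaf)
  # the marginal is returned for any assignment
  expect_equal(
    predict_distribution(tree, c(x1 = "1")),
    predict_distribution(tree)
  )
})

test_that("the depth limit bounds every root-to-leaf path", {
  withr::with_seed(11, {
    n <- 400
    x1 <- sample(c("0", "1"), n, TRUE)
    x2 <- sample(c("0", "1"), n, TRUE)
    x3 <- sample(c("0", "1"), n, TRUE)
    y <- ifelse(xor(xor(x1 == "1", x2 == "1"), x3 == "1"), "1", "0")
    df <- data.frame(x1, x2, x3, y)
  })
  for (lim in 0:3) {
    tree <- learn_tree(df, "y", c("x1", "x2", "x3"),
      depth_limit = lim, min_gain = 0
    )
    expect_lte(dn2cn:::tree_depth(tree), lim)
  }
})

test_that("an exactly irrelevant candidate never enters the tree", {
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      base <- data.frame(
        x = sample(c("0", "1"), 80, TRUE),
        y = sample(c("0", "1"), 80, TRUE)
      )
      base$y <- ifelse(base$x == "1" & stats::runif(80) < 0.9, "1", base$y)
    })
    # duplicating the data with z = 0 / z = 1 makes z exactly independent of
    # every variable in every context
    doubled <- rbind(
      cbind(base, z = "0", stringsAsFactors = FALSE),
      cbind(base, z = "1", stringsAsFactors = FALSE)
    )
    t_with <- learn_tree(doubled, "y", c("x", "z"))
    expect_false("z" %in% tree_parents(t_with))
    t_without <- learn_tree(base, "y", "x")
    expect_equal(tree_parents(t_with), tree_parents(t_without))
  }
})

test_that("depth limit zero gives the smoothed marginal", {
  df <- and_dataset(25)
  tree <- learn_tree(df, "y", c("x1", "x2"), depth_limit = 0, alpha = 0)
  expect_true(tree$node$leaf)
  expect_equal(unname(tree$node$prob), c(75, 25) / 100)
})

test_that("learning is invariant to row order", {
  df <- and_dataset(30)
  withr::with_seed(3, perm <- sample(nrow(df)))
  t1 <- learn_tree(df, "y", c("x1", "x2"))
  t2 <- learn_tree(df[perm, ], "y", c("x1", "x2"))
  expect_equal(t1$node, t2$node)
})

test_that("prediction demands the test variables on its path", {
  df <- and_dataset(50)
  tree <- learn_tree(df, "y", c("x1", "x2"))
  expect_error(predict_distribution(tree, c(x2 = "1")), "missing test variable")
  expect_error(
    predict_distribution(tree, c(x1 = "2", x2 = "1")),
    "unknown state"
  )
})

test_that("an empty candidate set is a marginal, not an error", {
  df <- and_dataset(10)
  tree <- learn_tree(df, "y", character(0))
  expect_true(tree$node$leaf)
  expect_error(learn_tree(df, "y", c("y", "x1")), "target")
})
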