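toy_xy <- function() {
  # printed 4-row toy table: P(x=1) = 1/2, P(y=1|x=1) = 1, P(y=1|x=0) = 1/2
  data.frame(x = c("0", "0", "1", "1"), y = c("0", "1", "1", "1"))
}

test_that("unsmoothed leaves equal empirical conditional frequencies", {
  net <- fit_parameters(
    toy_xy(), tibble::tibble(from = "x", to = "y"),
    alpha = 0
  )
  expect_equal(
    unname(predict_distribution(net$trees$y, c(x = "0"))),
    c(0.5, 0.5)
  )
  expect_equal(
    unname(predict_distribution(net$trees$y, c(x = "1"))),
    c(0, 1)
  )
})

test_that("a hand-multiplied two-variable likelihood is reproduced", {
  df <- toy_xy()
  net <- fit_parameters(df, tibble::tibble(from = "x", to = "y"), alpha = 0)
  # rows: (0,0) -> 1/2 * 1/2; (0,1) -> 1/2 * 1/2; (1,1) -> 1/2 * 1 (twice)
  expected <- log(0.25) + log(0.25) + 2 * log(0.5)
  expect_equal(log_likelihood(df, net), expected, tolerance = 1e-12)
})

test_that("uniform single-leaf CPDs give the closed-form likelihood", {
  m <- 10000
  cols <- lapply(1:8, function(i) rep(c("0", "1"), each = m / 2))
  names(cols) <- paste0("v", 1:8)
  df <- as.data.frame(cols)
  empty_dag <- tibble::tibble(from = character(0), to = character(0))
  net <- fit_parameters(df, empty_dag, alpha = 0)
  expect_equal(log_likelihood(df, net), -m * 8 * log(2), tolerance = 1e-8)
})

test_that("a parentless-only net reproduces the empirical entropy identity", {
  withr::with_seed(77, df <- random_dataset(500, c(2, 3, 4)))
  empty_dag <- tibble::tibble(from = character(0), to = character(0))
  net <- fit_parameters(df, empty_dag, alpha = 0)
  d <- as_discrete_data(df)
  expected <- 0
  for (v in variables(d)) {
    p <- tabulate(d$codes[, v], d$arity[[v]]) / d$m
    expected <- expected - d$m * sum(ifelse(p > 0, p * log(p), 0))
  }
  expect_equal(log_likelihood(df, net), -expected, tolerance = 1e-9)
})

test_that("adding a true parent never lowers the training likelihood", {
  net0 <- bundled_network("demo6")
  d <- forward_sample(net0, 2000, seed = 10)
  no_parent <- fit_parameters(
    d, tibble::tibble(from = character(0), to = character(0)),
    alpha = 0
  )
  with_parent <- fit_parameters(
    d, tibble::tibble(from = "B", to = "A"),
    alpha = 0
  )
  expect_gte(
    log_likelihood(d, with_parent),
    log_likelihood(d, no_parent) - 1e-9
  )
})

test_that("zero-probability observations give -Inf with a warning", {
  train <- data.frame(x = c("0", "0"), y = c("0", "0"))
  test <- data.frame(x = c("0", "1"), y = c("1", "0"))
  net <- fit_parameters(
    rbind(train, data.frame(x = "1", y = "1")),
    tibble::tibble(from = "x", to = "y"),
    alpha = 0
  )
  expect_warning(ll <- log_likelihood(test, net), "zero-probability")
  expect_identical(ll, -Inf)
  # smoothing keeps it finite
  net1 <- fit_parameters(
    rbind(train, data.frame(x = "1", y = "1")),
    tibble::tibble(from = "x", to = "y"),
    alpha = 1
  )
  expect_true(is.finite(log_likelihood(test, net1)))
})

test_that("forward sampling matches root marginals and is reproducible", {
  net <- ground_truth_network(
    "coin",
    levels = list(r = c("no", "yes")),
    parents = list(r = character(0)),
    cpt = list(r = matrix(c(0.7, 0.3), 1, dimnames = list(NULL, c("no", "yes"))))
  )
  d1 <- forward_sample(net, 10000, seed = 123)
  d2 <- forward_sample(net, 10000, seed = 123)
  expect_identical(d1, d2)
  freq <- mean(d1$r == "yes")
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(freq - 0.3), 3 * se)
})

test_that("deterministic CPTs sample a single repeated row", {
  net <- ground_truth_network(
    "det",
    levels = list(a = c("0", "1"), b = c("0", "1")),
    parents = list(a = character(0), b = "a"),
    cpt = list(
      a = matrix(c(0, 1), 1, dimnames = list(NULL, c("0", "1"))),
      b = matrix(c(1, 0, 0, 1), 2, dimnames = list(NULL, c("0", "1")))
    )
  )
  d <- forward_sample(net, 50, seed = 1)
  expect_true(all(d$a == "1"))
  expect_true(all(d$b == "1")) # b copies a deterministically
})

test_that("sampling from a fitted tree network matches its leaf laws", {
  net0 <- bundled_network("demo6")
  train <- forward_sample(net0, 4000, seed = 3)
  fit <- fit_parameters(train, network_edges(net0), alpha = 0)
  resampled <- forward_sample(fit, 8000, seed = 4)
  # the root-state frequency of C should match its fitted marginal
  p_fit <- predict_distribution(fit$trees$C)[["1"]]
  expect_lt(abs(mean(resampled$C == "1") - p_fit), 0.02)
})

test_that("fitting on the truth DAG recovers CPT entries at large n", {
  withr::with_seed(55, truth <- random_truth_network(6))
  d <- forward_sample(truth, 50000, seed = 56)
  fit <- fit_parameters(d, network_edges(truth), alpha = 0)
  worst <- 0
  for (v in truth$variables) {
    pa <- truth$parents[[v]]
    if (length(pa) == 0) {
      p_hat <- predict_distribution(fit$trees[[v]])
      worst <- max(worst, max(abs(p_hat - truth$cpt[[v]][1, names(p_hat)])))
    } else {
      configs <- expand.grid(lapply(truth$levels[pa], identity),
        stringsAsFactors = FALSE
      )
      for (r in seq_len(nrow(configs))) {
        assign_ <- stats::setNames(as.character(configs[r, ]), pa)
        p_hat <- predict_distribution(fit$trees[[v]], assign_)
        p_true <- truth$cpt[[v]][r, names(p_hat)]
        worst <- max(worst, max(abs(p_hat - p_true)))
      }
    }
  }
  expect_lt(worst, 0.05)
})
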