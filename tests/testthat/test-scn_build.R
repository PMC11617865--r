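resid_from <- function(values, ...) residualize(make_cohort(values, ...),
                                                covariate_names = "age")

test_that("covariance matrix rectifies negatives and zeroes the diagonal", {
  set.seed(2)
  n <- 20
  base <- rnorm(n)
  vals <- cbind(a = base + 0.01 * rnorm(n), b = base + 0.01 * rnorm(n),
                c = -base + 0.01 * rnorm(n), d = rnorm(n))
  rs <- resid_from(vals, age = rnorm(n))
  cv <- covariance_matrix(rs)
  expect_gt(cv$r["a", "b"], 0.99)         # near-identical columns
  expect_identical(cv$r["a", "c"], 0)     # negative correlation rectified
  expect_identical(unname(diag(cv$r)), rep(0, 4))
  expect_true(all(cv$r >= 0 & cv$r <= 1))
  expect_identical(cv$r, t(cv$r))
  # exactly identical columns give exactly 1
  vals2 <- cbind(a = base, b = base, c = rnorm(n))
  cv2 <- covariance_matrix(resid_from(vals2, age = rep(0, n) + rnorm(n)))
  expect_equal(cv2$r["a", "b"], 1, tolerance = 1e-12)
})

test_that("correlations match a brute-force Pearson oracle", {
  set.seed(8)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("r", 1:8)))
  rs <- resid_from(X, age = rnorm(30))
  cv <- covariance_matrix(rs)
  R <- rs$residuals
  for (i in 1:7) for (j in (i + 1):8) {
    x <- R[, i]; y <- R[, j]
    r_manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cv$r[i, j], max(0, r_manual), tolerance = 1e-10)
  }
})

test_that("rectification is idempotent", {
  set.seed(12)
  X <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("r", 1:6)))
  cv <- covariance_matrix(resid_from(X, age = rnorm(25)))
  r2 <- pmax(cv$r, 0); diag(r2) <- 0
  expect_identical(r2, cv$r)
})

test_that("zero-variance columns and absent groups are errors", {
  X <- cbind(a = rep(5, 10), b = rnorm(10))
  rs <- residualize(make_cohort(X, age = rnorm(10)), "age")
  expect_error(covariance_matrix(rs), "zero-variance.*a")
  X2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  rs2 <- residualize(make_cohort(X2, age = rnorm(10)), "age")
  expect_error(covariance_matrix(rs2, group = "nope"), "no subjects")
})

test_that("sparsity grid defaults to 36 values from 0.05 to 0.40", {
  g <- sparsity_grid()
  expect_length(g, 36)
  expect_equal(as.numeric(g)[1], 0.05)
  expect_equal(as.numeric(g)[36], 0.40)
  expect_true(all(diff(as.numeric(g)) > 0))
  expect_error(sparsity_grid(0.5, 0.4), "invalid")
  expect_error(sparsity_grid(0, 0.4), "invalid")
})

test_that("thresholding keeps round-half-up(s*N(N-1)/2) strongest edges", {
  set.seed(21)
  p <- 17
  X <- matrix(rnorm(40 * p), 40, p, dimnames = list(NULL, paste0("r", 1:p)))
  cv <- covariance_matrix(resid_from(X, age = rnorm(40)))
  adj <- threshold_at_sparsity(cv, 0.10)
  expect_identical(sum(adj) / 2, round(0.10 * 17 * 16 / 2))  # 14 edges
  expect_identical(adj, t(adj))
  expect_identical(unname(diag(adj)), rep(0L, p))
  # kept edges are the strongest positive ones
  kept <- cv$r[adj == 1]
  dropped <- cv$r[adj == 0 & upper.tri(cv$r) & cv$r > 0]
  expect_gte(min(kept), max(dropped))
  expect_error(threshold_at_sparsity(cv, 1.5), "sparsity")
})

test_that("all-negative matrices give empty graphs with a warning", {
  r <- matrix(0, 4, 4)   # rectified all-negative matrix: all zeros
  expect_warning(adj <- threshold_at_sparsity(r, 0.3), "positive")
  expect_identical(sum(adj), 0L)
})

test_that("saturating sparsity yields the complete graph", {
  set.seed(30)
  n <- 6
  base <- rnorm(50)
  X <- sapply(1:n, function(i) base + 0.2 * rnorm(50))  # all-positive cors
  colnames(X) <- paste0("r", 1:n)
  cv <- covariance_matrix(resid_from(X, age = rnorm(50)))
  adj <- threshold_at_sparsity(cv, 0.999)
  expect_identical(sum(adj) / 2, n * (n - 1) / 2)
})

test_that("thresholding is invariant to monotone transforms and nested", {
  set.seed(9)
  p <- 12
  X <- matrix(rnorm(30 * p), 30, p, dimnames = list(NULL, paste0("r", 1:p)))
  cv <- covariance_matrix(resid_from(X, age = rnorm(30)))
  grid <- sparsity_grid()
  stack <- build_graph_stack(cv, grid)
  expect_length(stack$adjacency, 36)
  # compositional equality with per-threshold calls
  for (k in c(1, 10, 36)) {
    expect_identical(stack$adjacency[[k]],
                     threshold_at_sparsity(cv, as.numeric(grid)[k]))
  }
  # edge counts non-decreasing, edge sets nested
  expect_true(all(diff(stack$edge_counts) >= 0))
  for (k in 2:36) {
    expect_true(all(stack$adjacency[[k - 1]] <= stack$adjacency[[k]]))
  }
  # strictly monotone transform of the positive entries: same graphs
  cv2 <- cv
  cv2$r <- cv$r^3
  stack2 <- build_graph_stack(cv2, grid)
  expect_identical(stack$adjacency, stack2$adjacency)
})

test_that("complete-graph stacks are never small-world; tiny n_null errors", {
  adj <- complete_graph(10)
  r <- matrix(0.5, 10, 10); diag(r) <- 0
  stack <- build_graph_stack(
    structure(list(r = r, r_raw = r, n_subjects = 20, group = "G",
                   atlas = NULL), class = "scn_cov"),
    sparsity_grid(0.989, 0.998, 0.003))   # round(s*45) = 45: complete
  # saturated: every graph complete; rewiring returns it unchanged; sigma = 1
  set.seed(1)
  expect_warning(frac <- check_small_world_range(stack, n_null = 20),
                 "small-world")
  expect_equal(as.numeric(frac), 0)
  expect_error(check_small_world_range(stack, n_null = 5), "n_null")
})
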