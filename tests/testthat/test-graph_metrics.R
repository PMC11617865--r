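path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
star4 <- rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))

test_that("metrics reproduce hand-computed values on canonical graphs", {
  k3 <- complete_graph(3)
  expect_identical(degree_centrality(k3), c(2L, 2L, 2L))
  expect_identical(degree_centrality(path3), c(1L, 2L, 1L))

  expect_equal(betweenness_centrality(path3), c(0, 1, 0))
  expect_equal(betweenness_centrality(star4), c(3, 0, 0, 0))

  k4 <- complete_graph(4)
  expect_equal(clustering_coefficients(k4)$Cp, 1)
  expect_equal(clustering_coefficients(star4)$Cp, 0)
  # triangle A,B,C plus pendant D-A: C_A = 1/3
  tri_pend <- rbind(c(0, 1, 1, 1), c(1, 0, 1, 0),
                    c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(clustering_coefficients(tri_pend)$ci[1], 1 / 3)

  expect_equal(characteristic_path_length(path3), 4 / 3)
  expect_equal(characteristic_path_length(k4), 1)
  two_k2 <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                  c(0, 0, 0, 1), c(0, 0, 1, 0))
  expect_equal(characteristic_path_length(two_k2), 1)  # finite pairs only

  expect_equal(global_efficiency(k4), 1)
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3)
  expect_warning(lp0 <- characteristic_path_length(matrix(0, 3, 3)),
                 "no edges")
  expect_true(is.nan(lp0))
})

test_that("asymmetric or non-binary input is rejected", {
  bad <- rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  expect_error(degree_centrality(bad), "symmetric")
  expect_error(betweenness_centrality(path3 * 2), "binary")
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    adj <- rand_adj(n, runif(1, 0.2, 0.7))
    expect_equal(as.numeric(degree_centrality(adj)), o_degree(adj))
    expect_equal(clustering_coefficients(adj)$ci, o_clustering(adj),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(characteristic_path_length(adj)),
                 o_lp(adj), tolerance = 1e-12)
    expect_equal(global_efficiency(adj), o_eglob(adj), tolerance = 1e-12)
    expect_equal(as.numeric(nodal_efficiency(adj)), o_nodal_eff(adj),
                 tolerance = 1e-12)
    expect_equal(as.numeric(local_efficiency(adj)), o_local_eff(adj),
                 tolerance = 1e-12)
    if (n <= 10) {
      expect_equal(as.numeric(betweenness_centrality(adj)),
                   o_betweenness(adj), tolerance = 1e-9)
    }
  }
})

test_that("metrics agree with igraph on moderate random graphs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(8:25, 1)
    adj <- rand_adj(n, 0.3)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(as.numeric(degree_centrality(adj)),
                 as.numeric(igraph::degree(g)))
    expect_equal(as.numeric(betweenness_centrality(adj)),
                 as.numeric(igraph::betweenness(g)), tolerance = 1e-9)
    ci <- igraph::transitivity(g, type = "local", isolates = "zero")
    # igraph defines local transitivity NaN->0 for deg<2 with isolates="zero"
    expect_equal(clustering_coefficients(adj)$ci, as.numeric(ci),
                 tolerance = 1e-12)
    D <- igraph::distances(g)
    finite <- is.finite(D) & D > 0
    expect_equal(suppressWarnings(characteristic_path_length(adj)),
                 mean(D[finite]), tolerance = 1e-12)
  }
})

test_that("efficiency strictly decreases when a bridge edge is removed", {
  adj <- rbind(c(0, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0))
  e1 <- global_efficiency(adj)
  adj2 <- adj; adj2[2, 3] <- adj2[3, 2] <- 0
  expect_lt(global_efficiency(adj2), e1)
})

test_that("AUC matches closed forms and a refinement oracle", {
  g <- sparsity_grid()
  expect_equal(auc_over_grid(rep(3, 36), g), 0.35 * 3, tolerance = 1e-12)
  expect_equal(auc_over_grid(as.numeric(g), g), (0.40^2 - 0.05^2) / 2,
               tolerance = 1e-12)
  # random curve: trapezoid equals fine-grid integration of the
  # piecewise-linear interpolant
  set.seed(4)
  y <- runif(36)
  s <- as.numeric(g)
  fine <- seq(0.05, 0.40, length.out = 20001)
  yi <- approx(s, y, xout = fine)$y
  riemann <- sum((yi[-1] + yi[-length(yi)]) / 2) * diff(fine[1:2])
  expect_equal(auc_over_grid(y, g), riemann, tolerance = 1e-6)

  # NaN handling: largest NaN-free suffix with a warning; all-NaN errors
  y2 <- y; y2[1:3] <- NaN
  expect_warning(a2 <- auc_over_grid(y2, g), "leading")
  expect_equal(a2, auc_over_grid(y[4:36], s[4:36]), tolerance = 1e-12)
  expect_error(auc_over_grid(rep(NaN, 36), g), "all curve values")
})

test_that("metric curves are deterministic and complete-stack calibrated", {
  r <- matrix(0.5, 8, 8); diag(r) <- 0
  cv <- structure(list(r = r, r_raw = r, n_subjects = 20, group = "G",
                       atlas = NULL), class = "scn_cov")
  stack <- build_graph_stack(cv, sparsity_grid(0.983, 0.999, 0.001))
  # round(s*28) = 28 at every s: all graphs complete
  expect_true(all(stack$edge_counts == 28))
  mc <- compute_metric_curves(stack, n_null = 20, seed = 5)
  span <- max(stack$sparsity) - min(stack$sparsity)
  expect_equal(unname(mc$auc_global["sigma"]), span, tolerance = 1e-10)
  expect_true(all(abs(mc$global$sigma - 1) < 1e-12))
  expect_equal(unname(mc$auc_global["Cp"]), span * 1, tolerance = 1e-10)
  expect_equal(unname(mc$auc_global["Lp"]), span * 1, tolerance = 1e-10)
  # bitwise reproducibility for a fixed seed
  mc2 <- compute_metric_curves(stack, n_null = 20, seed = 5)
  expect_identical(mc, mc2)
})
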