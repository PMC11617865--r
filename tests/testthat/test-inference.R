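test_that("BH adjustment matches the hand step-up computation", {
  out <- fdr_bh(numeric(0))
  expect_length(out$p_adjusted, 0)
  expect_length(out$rejected, 0)

  out <- fdr_bh(rep(0.001, 10), q = 0.05)
  expect_true(all(out$rejected))

  out <- fdr_bh(c(0.01, 0.04, 0.03, 0.005))
  expect_equal(out$p_adjusted, c(0.02, 0.04, 0.04, 0.02))

  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("edge backbone follows the correlation t-test", {
  r <- matrix(0, 5, 5)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.3
  r[4, 5] <- r[5, 4] <- 1.0
  cv <- structure(list(r = r, r_raw = r, n_subjects = 40, group = "G",
                       atlas = NULL), class = "scn_cov")
  mask <- edge_backbone(cv, alpha = 0.001)
  # t-distribution tail oracle
  p_of <- function(rr, n) 2 * pt(rr * sqrt((n - 2) / (1 - rr^2)), n - 2,
                                 lower.tail = FALSE)
  expect_lt(p_of(0.9, 40), 0.001)
  expect_true(mask[1, 2])
  expect_gt(p_of(0.3, 40), 0.001)
  expect_false(mask[1, 3])
  expect_false(mask[2, 3])          # r = 0 never retained
  expect_true(mask[4, 5])           # r = 1 retained as p = 0
  expect_false(any(diag(mask)))
  # monotone in alpha: increasing alpha never removes a retained edge
  m1 <- edge_backbone(cv, alpha = 1e-4)
  m2 <- edge_backbone(cv, alpha = 1e-2)
  expect_true(all(m2[m1]))
})

test_that("2+2 unpaired design matches exhaustive enumeration by hand", {
  set.seed(61)
  p <- 6
  vals <- matrix(rnorm(4 * p, 100, 10), 4,
                 dimnames = list(NULL, paste0("roi", 1:p)))
  cA <- make_cohort(vals[1:2, ], group = "A", age = c(55, 62),
                    icv = c(1.4e6, 1.5e6))
  cB <- make_cohort(vals[3:4, ], group = "B", age = c(58, 60),
                    icv = c(1.45e6, 1.42e6))
  cB$subjects$subject_id <- paste0("B_", cB$subjects$subject_id)
  rownames(cB$values) <- cB$subjects$subject_id
  grid <- sparsity_grid(0.2, 0.4, 0.1)

  expect_warning(
    res <- permutation_test_unpaired(cA, cB, grid = grid, n_perm = 100,
                                     properties = "Cp",
                                     covariate_names = "age", seed = 7),
    "fewer than 4")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(4, 2))

  # independent enumeration: residualize once, then loop all 6 relabelings
  resid <- residualize(bind_cohorts(cA, cB), "age")$residuals
  cp_auc <- function(rows) {
    r <- suppressWarnings(cor(resid[rows, ])); r[!is.finite(r)] <- 0
    r <- pmax(r, 0); diag(r) <- 0
    cps <- sapply(as.numeric(grid), function(s)
      mean(o_clustering(suppressWarnings(threshold_at_sparsity(r, s)))))
    sum(diff(as.numeric(grid)) * (head(cps, -1) + cps[-1]) / 2)
  }
  sets <- combn(4, 2)
  diffs <- apply(sets, 2, function(A)
    cp_auc(A) - cp_auc(setdiff(1:4, A)))
  obs <- cp_auc(1:2) - cp_auc(3:4)
  row <- res$results[res$results$property == "Cp", ]
  expect_equal(row$observed_diff, obs, tolerance = 1e-12)
  expect_equal(row$p_raw, mean(abs(diffs) >= abs(obs)), tolerance = 1e-12)

  # swapping group roles negates the difference, p unchanged
  expect_warning(
    res2 <- permutation_test_unpaired(cB, cA, grid = grid, n_perm = 100,
                                      properties = "Cp",
                                      covariate_names = "age", seed = 7),
    "fewer than 4")
  row2 <- res2$results[res2$results$property == "Cp", ]
  expect_equal(row2$observed_diff, -row$observed_diff, tolerance = 1e-12)
  expect_equal(row2$p_raw, row$p_raw, tolerance = 1e-12)
})

test_that("a planted extreme difference attains the minimal p-value", {
  strong <- synthetic_spec(n_subjects = 10, group_label = "S",
                           blocks = covnet:::.fixture_blocks_17(0.9),
                           r0 = 0.3, seed = 31)
  flat <- synthetic_spec(n_subjects = 10, group_label = "F",
                         blocks = list(), r0 = 0, seed = 32)
  cs <- generate_cohort(strong); cf <- generate_cohort(flat)
  res <- suppressWarnings(permutation_test_unpaired(
    cs, cf, grid = sparsity_grid(0.1, 0.3, 0.1), n_perm = 99,
    properties = "Cp", seed = 5))
  expect_false(res$exhaustive)
  row <- res$results[res$results$property == "Cp", ]
  expect_equal(row$p_raw, 1 / (99 + 1))
})

test_that("permutation results respect the p-value floor and FDR ordering", {
  fx <- fixture_cohort("effect_17", n_per_group = 12, seed = 3)
  res <- suppressWarnings(permutation_test_unpaired(
    fx$A, fx$B, grid = sparsity_grid(0.1, 0.3, 0.1), n_perm = 99,
    properties = c("Cp", "Eglob", "degree"), seed = 11))
  tab <- res$results
  expect_true(all(tab$p_raw >= 1 / (res$n_perm + 1), na.rm = TRUE))
  nod <- tab[tab$node != "global", ]
  expect_true(all(nod$p_fdr >= nod$p_raw - 1e-12, na.rm = TRUE))
  expect_identical(nrow(nod), 17L)
  # overlapping subject sets are rejected
  expect_error(permutation_test_unpaired(fx$A, fx$A, n_perm = 10, seed = 1),
               "overlap")
})

test_that("identical pair members give zero difference and p = 1", {
  set.seed(4)
  K <- 6; p <- 8
  v <- matrix(rnorm(K * p, 1000, 80), K,
              dimnames = list(NULL, paste0("roi", 1:p)))
  vals <- rbind(v, v)
  rownames(vals) <- c(sprintf("P%02d_s1", 1:K), sprintf("P%02d_s2", 1:K))
  co <- make_cohort(vals, group = rep(c("scan1", "scan2"), each = K),
                    age = rep(rnorm(K, 60, 8), 2),
                    icv = rep(rnorm(K, 1.4e6, 1e5), 2),
                    pair_id = rep(sprintf("P%02d", 1:K), 2))
  res <- permutation_test_paired(co, grid = sparsity_grid(0.2, 0.4, 0.1),
                                 n_perm = 100, properties = "Cp", seed = 2)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 2^K)
  row <- res$results[res$results$property == "Cp", ]
  expect_equal(row$observed_diff, 0, tolerance = 1e-12)
  expect_equal(row$p_raw, 1)
})

test_that("paired Monte Carlo agrees with exhaustive enumeration", {
  co <- make_paired_cohort(n_pairs = 12, effect = -0.2,
                           rho_within_subject = 0.8, seed = 9,
                           spec = synthetic_spec(
                             blocks = covnet:::.fixture_blocks_17(0.7),
                             r0 = 0.1))
  grid <- sparsity_grid(0.15, 0.35, 0.1)
  ex <- permutation_test_paired(co, grid = grid, n_perm = 5000,
                                properties = "Cp", seed = 1)
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, 2^12)
  mc <- permutation_test_paired(co, grid = grid, n_perm = 2000,
                                properties = "Cp", seed = 3)
  expect_false(mc$exhaustive)
  expect_equal(mc$results$p_raw[1], ex$results$p_raw[1], tolerance = 0.02)
})

test_that("the paired power scenario detects the planted follow-up loss", {
  # 23 pairs (follow-up-sized cohort) with a broad covariance collapse:
  # the planted Cp-AUC reduction should reach p < 0.05 in >= 80% of runs
  grid <- sparsity_grid(0.10, 0.30, 0.05)
  ps <- sapply(1:100, function(i) {
    co <- fixture_cohort("paired_23", seed = 50000 + i)
    res <- suppressWarnings(permutation_test_paired(
      co, grid = grid, n_perm = 300, properties = "Cp", seed = 60000 + i))
    res$results$p_raw[1]
  })
  expect_gte(mean(ps < 0.05), 0.80)
})

test_that("incomplete pairs are named in the error", {
  co <- fixture_cohort("paired_8", seed = 2)
  broken <- structure(list(subjects = co$subjects[-1, ],
                           values = co$values[-1, ],
                           measure_kind = co$measure_kind,
                           atlas = co$atlas), class = "cohort")
  expect_error(permutation_test_paired(broken, n_perm = 10, seed = 1),
               "P001")
})
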