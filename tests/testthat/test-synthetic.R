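test_that("generation is deterministic per seed with independent streams", {
  sp <- synthetic_spec(n_subjects = 12, seed = 44,
                       blocks = list(list(nodes = 1:4, r = 0.6)))
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  fx1 <- fixture_cohort("null_17", n_per_group = 8, seed = 5)
  fx2 <- fixture_cohort("null_17", n_per_group = 8, seed = 5)
  expect_identical(fx1$A, fx2$A)
  expect_identical(fx1$B, fx2$B)
  expect_false(identical(fx1$A$values, fx1$B$values))
})

test_that("planted block correlations are recovered at large n", {
  sp <- synthetic_spec(n_subjects = 500, seed = 77, r0 = 0.1,
                       blocks = list(list(nodes = 1:6, r = 0.6)))
  co <- generate_cohort(sp)
  rs <- residualize(co)
  cm <- cor(rs$residuals)
  within <- cm[1:6, 1:6][upper.tri(matrix(0, 6, 6))]
  # Fisher-z SE at n=500 is ~0.045; 0.08 is a ~2 SE band
  expect_true(all(abs(within - 0.6) < 0.08))
  outside <- cm[7:17, 7:17][upper.tri(matrix(0, 11, 11))]
  expect_true(all(abs(outside - 0.1) < 0.15))
})

test_that("covariate effects are planted and removable", {
  # beta_age = 0: OLS slope of ROI on age is 0 within 2 SE
  sp0 <- synthetic_spec(n_subjects = 400, seed = 13, beta_age = 0,
                        beta_icv = 0)
  co0 <- generate_cohort(sp0)
  fit <- lm(co0$values[, 1] ~ co0$subjects$age)
  sm <- summary(fit)$coefficients
  expect_lt(abs(sm[2, 1]), 2 * sm[2, 2])

  # planted confounds induce age correlation; residualization removes it
  sp <- synthetic_spec(n_subjects = 500, seed = 14, beta_age = -25)
  co <- generate_cohort(sp)
  raw_cor <- cor(co$values[, 3], co$subjects$age)
  expect_lt(raw_cor, -0.2)
  rs <- residualize(co)
  expect_true(all(abs(cor(rs$residuals, co$subjects$age)) < 0.05))
})

test_that("spec validation rejects bad blocks", {
  expect_error(synthetic_spec(blocks = list(list(nodes = 1:30, r = 0.5))),
               "outside")
  expect_error(synthetic_spec(blocks = list(list(nodes = 1:4, r = 0.5),
                                            list(nodes = 4:8, r = 0.5))),
               "overlap")
  expect_error(synthetic_spec(blocks = list(list(nodes = 1:4, r = 0.05)),
                              r0 = 0.1), "r0 <= r")
})

test_that("group pairs share the covariate model and differ as planted", {
  fx <- fixture_cohort("effect_17", n_per_group = 60, seed = 21)
  rs <- residualize(bind_cohorts(fx$A, fx$B))
  cmA <- cor(rs$residuals[rs$group_labels == "A", ])
  cmB <- cor(rs$residuals[rs$group_labels == "B", ])
  blockA <- mean(cmA[3:8, 3:8][upper.tri(matrix(0, 6, 6))])
  blockB <- mean(cmB[3:8, 3:8][upper.tri(matrix(0, 6, 6))])
  expect_gt(blockA, 0.5)
  expect_lt(blockB, 0.35)
  # mismatched covariate models are rejected
  sA <- synthetic_spec(group_label = "A")
  sB <- synthetic_spec(group_label = "B", beta_age = -99)
  expect_error(make_group_pair(sA, sB), "covariate model")
})

test_that("paired cohorts respect rho and the planted scan-2 shift", {
  base <- synthetic_spec(blocks = covnet:::.fixture_blocks_17(0.7), r0 = 0.1)
  co <- make_paired_cohort(n_pairs = 300, effect = c(0, -0.35, 0, 0),
                           rho_within_subject = 0.8, seed = 6, spec = base)
  expect_true(all(table(co$subjects$pair_id) == 2))
  # shared age/ICV across scans confound raw correlations; measure the
  # latent structure on residualized values
  rsv <- residualize(co)$residuals
  v1 <- rsv[co$subjects$group == "scan1", ]
  v2 <- rsv[co$subjects$group == "scan2", ]
  # per-ROI within-subject correlation near rho
  wc <- sapply(1:17, function(j) cor(v1[, j], v2[, j]))
  expect_true(all(abs(wc - 0.8) < 0.1))
  # limbic block correlation reduced at scan 2 only
  c1 <- cor(v1[, 9:12]); c2 <- cor(v2[, 9:12])
  expect_gt(mean(c1[upper.tri(c1)]), 0.6)
  expect_lt(mean(c2[upper.tri(c2)]), 0.55)

  # near-identical scans when rho ~ 1 and no effect
  co2 <- make_paired_cohort(n_pairs = 10, effect = 0,
                            rho_within_subject = 0.99, seed = 8, spec = base)
  res <- permutation_test_paired(co2, grid = sparsity_grid(0.2, 0.4, 0.1),
                                 n_perm = 200, properties = c("Cp", "Eglob"),
                                 seed = 3)
  expect_true(all(abs(res$results$observed_diff) < 0.05))

  # an unreachable scan-2 correlation target is rejected
  expect_error(make_paired_cohort(n_pairs = 5, effect = -0.65,
                                  rho_within_subject = 0.95, spec = base),
               "invalid correlation target")
})

test_that("cohort tables round-trip through the file readers", {
  fx <- fixture_cohort("null_17", n_per_group = 6, seed = 9)
  sp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tables(fx$A, sp, cp)
  tb <- read_stats_table(sp, "volume")
  covs <- read_covariates(cp)
  co <- assemble_cohort(tb, covs, fx$A$atlas)
  expect_equal(co$values, fx$A$values, tolerance = 1e-9)
  expect_equal(co$subjects$age, fx$A$subjects$age, tolerance = 1e-9)
  expect_equal(co$subjects$icv, fx$A$subjects$icv, tolerance = 1e-9)
})
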