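test_that("noise-free simulation is exact and seeds are reproducible", {
  ts <- data.frame(tissue = c("liver", "lung"), n_cancer = 3L, n_normal = 3L)
  cfg <- simulationConfig(n_probesets = 4L, tissue_sizes = ts,
                          experiments_per_tissue = 2L,
                          grand_mean_range = c(5, 5),
                          beta_nonnull_fraction = 1, beta_location = 2,
                          beta_scale = 0, var_tissue = 0,
                          var_tissue_disease = 0, var_experiment = 0,
                          var_experiment_disease = 0, var_residual = 0,
                          seed = 1L)
  sim <- simulateDataset(cfg)
  v <- exprValues(sim$es)
  cancer <- diseaseStatus(sim$es) == "cancer"
  for (i in 1:4) {
    expect_equal(unname(v[i, cancer]),
                 rep(unname(5 + sim$truth$beta[i]), sum(cancer)))
    expect_equal(unname(v[i, !cancer]), rep(5, sum(!cancer)))
  }
  expect_true(all(abs(sim$truth$beta) == 2))

  sim2 <- simulateDataset(cfg)
  expect_identical(exprValues(sim2$es), v)  # bitwise seed contract

  cfg2 <- cfg; cfg2@seed <- 2L
  expect_false(identical(exprValues(simulateDataset(cfg2)$es), v))
})

test_that("residual-only generation has unit within-status variance", {
  ts <- data.frame(tissue = "t1", n_cancer = 2500L, n_normal = 2500L)
  cfg <- simulationConfig(n_probesets = 1L, tissue_sizes = ts,
                          experiments_per_tissue = 3L,
                          grand_mean_range = c(7, 7),
                          beta_nonnull_fraction = 0,
                          var_tissue = 0, var_tissue_disease = 0,
                          var_experiment = 0, var_experiment_disease = 0,
                          var_residual = 1, seed = 5L)
  sim <- simulateDataset(cfg)
  y <- exprValues(sim$es)[1L, ]
  cancer <- diseaseStatus(sim$es) == "cancer"
  # chi-square 99% interval for the sample variance at n = 2500 per class
  expect_gt(var(y[cancer]), 0.92)
  expect_lt(var(y[cancer]), 1.08)
  expect_gt(var(y[!cancer]), 0.92)
  expect_lt(var(y[!cancer]), 1.08)
})

test_that("group-level variance decomposition matches configured components", {
  # many tissues -> the spread of tissue effects recovers var_tissue;
  # many experiments -> experiment-mean deviations recover var_experiment
  ts <- data.frame(tissue = sprintf("t%03d", 1:200),
                   n_cancer = 15L, n_normal = 15L)
  cfg <- simulationConfig(n_probesets = 1L, tissue_sizes = ts,
                          experiments_per_tissue = 1L,
                          grand_mean_range = c(8, 8),
                          beta_nonnull_fraction = 0,
                          var_tissue = 1, var_tissue_disease = 0,
                          var_experiment = 0.5, var_experiment_disease = 0,
                          var_residual = 0.05, seed = 9L)
  sim <- simulateDataset(cfg)
  re <- sim$truth$random_effects
  expect_lt(abs(var(as.vector(re$tissue)) - 1) / 1, 0.15)
  expect_lt(abs(var(as.vector(re$experiment)) - 0.5) / 0.5, 0.15)
  # and the realized effects surface in the data: per-tissue means vary by
  # var_tissue + var_experiment (one experiment per tissue) + residual/30
  tis_means <- tapply(exprValues(sim$es)[1L, ], tissueType(sim$es), mean)
  expect_lt(abs(var(tis_means) - 1.5) / 1.5, 0.15)
})

test_that("null simulation is null and its model p-values are uniform", {
  ts <- data.frame(tissue = sprintf("t%02d", 1:15),
                   n_cancer = 20L, n_normal = 20L)
  cfg <- simulationConfig(n_probesets = 60L, tissue_sizes = ts,
                          experiments_per_tissue = 2L,
                          beta_nonnull_fraction = 0.3, seed = 2L)
  sim <- simulateNull(cfg)
  expect_true(all(sim$truth$beta == 0))
  expect_true(all(sim$truth$is_null))

  # KS uniformity across seeded repetitions (a small slice of the
  # full-scale calibration exercised in the acceptance suite)
  pass <- vapply(1:3, function(s) {
    cfg@seed <- as.integer(100 + s)
    nsim <- simulateNull(cfg)
    p <- significanceTable(fitAll(nsim$es, 0.01))$p_value
    stats::ks.test(p, "punif")$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 2L)
})

test_that("the fitter recovers truth exactly on noise-free data", {
  ts <- data.frame(tissue = c("a", "b", "c"), n_cancer = 4L, n_normal = 4L)
  cfg <- simulationConfig(n_probesets = 3L, tissue_sizes = ts,
                          experiments_per_tissue = 2L,
                          grand_mean_range = c(6, 6),
                          beta_nonnull_fraction = 1, beta_location = 1.5,
                          beta_scale = 0, var_tissue = 0,
                          var_tissue_disease = 0, var_experiment = 0,
                          var_experiment_disease = 0, var_residual = 0,
                          seed = 3L)
  sim <- simulateDataset(cfg)
  for (i in 1:3) {
    fit <- fitProbeset(exprValues(sim$es)[i, ], sim$es)
    expect_equal(fit@beta_hat, unname(sim$truth$beta[i]), tolerance = 1e-8)
    expect_lt(max(fit@varcomps[1:4]), 1e-6)
  }
})

test_that("invalid configurations are rejected", {
  ts <- data.frame(tissue = "a", n_cancer = 0L, n_normal = 3L)
  expect_error(simulationConfig(tissue_sizes = ts), "at least one")
  expect_error(simulationConfig(beta_nonnull_fraction = 1.5), "\\[0,1\\]")
  expect_error(simulationConfig(var_residual = -1), "non-negative")
})
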