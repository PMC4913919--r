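test_that("the REML fitter interpolates noise-free data exactly", {
  tissue <- rep(c("a", "b"), each = 6)
  experiment <- paste0(tissue, rep_len(1:2, 12))
  disease <- rep(c("cancer", "normal"), 6)
  y <- 5 + 2 * (disease == "cancer")
  fit <- fitProbeset(y, data.frame(tissue, experiment,
                                   disease_status = disease))
  expect_equal(fit@beta_hat, 2, tolerance = 1e-8)
  expect_equal(fit@mu_hat, 5, tolerance = 1e-8)
  expect_lt(max(fit@varcomps[1:4]), 1e-6)
  expect_true(fit@converged)
})

test_that("fixed-component fits equal the dense GLS oracle", {
  ts <- data.frame(tissue = c("a", "b", "c"), n_cancer = 8L, n_normal = 8L)
  cfg <- simulationConfig(n_probesets = 4L, tissue_sizes = ts,
                          experiments_per_tissue = 2L,
                          beta_nonnull_fraction = 0.5, seed = 41L)
  sim <- simulateDataset(cfg)
  vc <- c(tissue = 1, tissue_disease = 0.25, experiment = 0.5,
          experiment_disease = 0.1, residual = 0.5)
  for (i in 1:4) {
    y <- exprValues(sim$es)[i, ]
    fit <- fitProbeset(y, sim$es, varcomps = vc)
    oracle <- gls_oracle(y, tissueType(sim$es), experimentId(sim$es),
                         diseaseStatus(sim$es), vc)
    expect_lt(abs(fit@beta_hat - oracle$beta) / abs(oracle$beta), 1e-6)
    expect_lt(abs(fit@se_beta - oracle$se) / oracle$se, 1e-6)
    expect_lt(abs(fit@mu_hat - oracle$mu) / max(abs(oracle$mu), 1), 1e-6)
  }
})

test_that("REML estimates agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  ts <- data.frame(tissue = c("a", "b", "c", "d"), n_cancer = 10L,
                   n_normal = 10L)
  cfg <- simulationConfig(n_probesets = 3L, tissue_sizes = ts,
                          experiments_per_tissue = 2L,
                          beta_nonnull_fraction = 1, seed = 42L)
  sim <- simulateDataset(cfg)
  for (i in 1:3) {
    y <- exprValues(sim$es)[i, ]
    fit <- fitProbeset(y, sim$es)
    d <- data.frame(y = y, tissue = tissueType(sim$es),
                    experiment = experimentId(sim$es),
                    disease = factor(diseaseStatus(sim$es),
                                     levels = c("normal", "cancer")))
    lf <- suppressWarnings(suppressMessages(lme4::lmer(
      y ~ disease + (1 | tissue) + (1 | tissue:disease) +
        (1 | experiment) + (1 | experiment:disease),
      data = d, REML = TRUE)))
    expect_equal(fit@beta_hat, unname(lme4::fixef(lf)[2L]), tolerance = 1e-4)
    expect_equal(fit@se_beta, sqrt(as.numeric(vcov(lf)[2L, 2L])),
                 tolerance = 1e-3)
  }
})

test_that("REML solutions are stationary points of the criterion", {
  ts <- data.frame(tissue = sprintf("t%d", 1:5), n_cancer = 8L, n_normal = 8L)
  cfg <- simulationConfig(n_probesets = 3L, tissue_sizes = ts,
                          experiments_per_tissue = 2L, seed = 44L)
  sim <- simulateDataset(cfg)
  es <- sim$es
  design <- oncomap:::.prepDesign(tissueType(es), experimentId(es),
                                  diseaseStatus(es))
  st <- oncomap:::.probesetStats(design, exprValues(es))
  for (i in 1:3) {
    fit <- oncomap:::.fitCore(design, st$ZtY[i, ], st$XtY[i, ], st$yty[i])
    f0 <- oncomap:::.remlCriterion(fit$theta, design, st$ZtY[i, ],
                                   st$XtY[i, ], st$yty[i])
    for (r in 1:4) for (d in c(log(1.01), -log(1.01))) {
      th <- fit$theta
      th[r] <- min(max(th[r] + d, log(1e-10)), log(1e6))
      f1 <- oncomap:::.remlCriterion(th, design, st$ZtY[i, ],
                                     st$XtY[i, ], st$yty[i])
      expect_gte(f1, f0 - 1e-6)
    }
  }
})

test_that("location/scale changes act on beta as expected and leave t alone", {
  ts <- data.frame(tissue = c("a", "b", "c"), n_cancer = 8L, n_normal = 8L)
  cfg <- simulationConfig(n_probesets = 1L, tissue_sizes = ts,
                          experiments_per_tissue = 2L,
                          beta_nonnull_fraction = 1, seed = 45L)
  sim <- simulateDataset(cfg)
  y <- exprValues(sim$es)[1L, ]
  f1 <- fitProbeset(y, sim$es)
  f2 <- fitProbeset(2.5 * y + 7, sim$es)
  expect_equal(f2@beta_hat, 2.5 * f1@beta_hat, tolerance = 1e-5)
  t1 <- testDiseaseEffect(f1); t2 <- testDiseaseEffect(f2)
  expect_equal(t2$t_stat, t1$t_stat, tolerance = 1e-5)
  expect_equal(t2$p_value, t1$p_value, tolerance = 1e-4)
})

test_that("degenerate designs are rejected with the factor named", {
  ann <- data.frame(tissue = rep("a", 12),
                    experiment = rep(c("e1", "e2"), 6),
                    disease_status = rep(c("cancer", "normal"), each = 6))
  expect_error(fitProbeset(rnorm(12), ann), "tissue")
  ann2 <- ann; ann2$tissue <- rep(c("a", "b"), 6); ann2$experiment <- "e1"
  expect_error(fitProbeset(rnorm(12), ann2), "experiment")
  ann3 <- ann2; ann3$experiment <- rep(c("e1", "e2"), 6)
  ann3$disease_status <- "cancer"
  expect_error(fitProbeset(rnorm(12), ann3), "disease")
})

test_that("the approximate t test uses N - 2 degrees of freedom", {
  fit <- new("MixedModelFit", beta_hat = 0, se_beta = 0.5, mu_hat = 1,
             varcomps = c(tissue = 1, tissue_disease = 0, experiment = 0,
                          experiment_disease = 0, residual = 1),
             reml_criterion = 0, converged = TRUE, n_obs = 100L)
  tr <- testDiseaseEffect(fit)
  expect_equal(tr$df, 98L)
  expect_equal(tr$p_value, 1)  # beta = 0 is maximally null

  # two-sided tail against a quadrature oracle at t = 2, df = 10
  fit2 <- fit; fit2@beta_hat <- 1; fit2@se_beta <- 0.5; fit2@n_obs <- 12L
  tr2 <- testDiseaseEffect(fit2)
  dens <- function(x) dt(x, df = 10)
  tail_right <- integrate(dens, 2, Inf, rel.tol = 1e-12)$value
  expect_equal(tr2$p_value, 2 * tail_right, tolerance = 1e-9)

  fit3 <- fit; fit3@converged <- FALSE
  expect_error(testDiseaseEffect(fit3), "converge")
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(46)
  p <- runif(50)
  # brute-force min-over-suffix oracle
  o <- order(p)
  m <- length(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  oracle <- numeric(m); oracle[o] <- q_sorted
  expect_equal(bhAdjust(p), oracle)
})

test_that("fitAll ranks by p, adjusts across probesets and recovers signal", {
  ts <- data.frame(tissue = sprintf("t%02d", 1:15), n_cancer = 20L,
                   n_normal = 20L)
  cfg <- simulationConfig(n_probesets = 100L, tissue_sizes = ts,
                          experiments_per_tissue = 2L,
                          beta_nonnull_fraction = 0.1,
                          beta_location = 3 * sqrt(0.5), beta_scale = 0,
                          seed = 47L)
  sim <- simulateDataset(cfg)
  res <- fitAll(sim$es, alpha = 0.01)
  tab <- significanceTable(res)
  expect_identical(tab$probeset_id, probesetIds(sim$es))
  conv <- tab$converged
  expect_equal(tab$p_adjusted[conv], bhAdjust(tab$p_value[conv]))
  expect_equal(order(tab$p_value[conv]), order(tab$rank[conv]))
  expect_true(all(tab$p_adjusted >= tab$p_value, na.rm = TRUE))

  # power: at |beta| = 3 sigma and 20 samples per class, at least 80% of
  # nonnull probesets are recovered
  nonnull <- !sim$truth$is_null
  expect_gte(sum(nonnull), 5L)
  recovered <- tab$significant[nonnull]
  expect_gte(mean(recovered), 0.8)
  # and the effect-size signs are recovered too
  expect_true(all(sign(tab$beta_hat[nonnull & tab$significant]) ==
                    sign(sim$truth$beta[nonnull & tab$significant])))
})
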