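# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# A small annotated set built by hand: `groups` is a named list mapping a
# biological-group label to the number of samples; tissue/experiment/disease
# can be vectors over samples or derived from the group label
# ("tissue_status" convention).
make_es <- function(values, groups, tissue = NULL, experiment = NULL,
                    disease = NULL) {
  n <- sum(unlist(groups))
  stopifnot(ncol(values) == n)
  grp <- rep(names(groups), unlist(groups))
  if (is.null(tissue)) tissue <- sub("_[^_]*$", "", grp)
  if (is.null(disease)) {
    disease <- sub("^.*_", "", grp)
    disease[!disease %in% c("normal", "cancer", "other")] <- "other"
  }
  if (is.null(experiment)) experiment <- "E1"
  colnames(values) <- sprintf("s%03d", seq_len(n))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  AnnotatedExpressionSet(values, data.frame(
    sample_id = colnames(values), biological_group = grp, tissue = tissue,
    experiment = experiment, disease_status = disease,
    stringsAsFactors = FALSE))
}

# Random compendium with tissue_status groups; each tissue gets both
# statuses and two experiments.
random_es <- function(n_probesets, tissues = 3L, per_class = 4L, seed = 1L) {
  set.seed(seed)
  tissue_names <- sprintf("tis%02d", seq_len(tissues))
  groups <- as.list(rep(per_class, 2L * tissues))
  names(groups) <- as.vector(outer(tissue_names, c("cancer", "normal"),
                                   paste, sep = "_"))
  n <- sum(unlist(groups))
  values <- matrix(rnorm(n_probesets * n, mean = 8, sd = 2), n_probesets, n)
  grp <- rep(names(groups), unlist(groups))
  tissue <- sub("_[^_]*$", "", grp)
  experiment <- paste0(tissue, "_e", rep_len(1:2, n))
  make_es(values, groups, tissue = tissue, experiment = experiment)
}

# Dense GLS oracle: builds the full n x n covariance from the random-effect
# design and solves the generalized least-squares normal equations
# directly. Independent of the package's Woodbury/blockwise path.
gls_oracle <- function(y, tissue, experiment, disease, varcomps) {
  n <- length(y)
  ind <- function(f) {
    f <- factor(f)
    m <- matrix(0, n, nlevels(f))
    m[cbind(seq_len(n), as.integer(f))] <- 1
    m
  }
  V <- varcomps[["tissue"]] * tcrossprod(ind(tissue)) +
    varcomps[["tissue_disease"]] * tcrossprod(ind(paste(tissue, disease))) +
    varcomps[["experiment"]] * tcrossprod(ind(experiment)) +
    varcomps[["experiment_disease"]] *
      tcrossprod(ind(paste(experiment, disease))) +
    varcomps[["residual"]] * diag(n)
  X <- cbind(1, as.numeric(disease == "cancer"))
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  list(beta = beta[2L], mu = beta[1L], se = sqrt(solve(XtViX)[2L, 2L]))
}

# One shared spiked-signal permutation run (cached: built on first use,
# reused by the permutation invariants and the export-structure checks).
.spiked_cache <- new.env(parent = emptyenv())
spiked_perm_run <- function() {
  if (!is.null(.spiked_cache$run)) return(.spiked_cache$run)
  ts <- data.frame(tissue = sprintf("t%02d", 1:8),
                   n_cancer = 20L, n_normal = 20L)
  cfg <- simulationConfig(n_probesets = 100L, tissue_sizes = ts,
                          experiments_per_tissue = 2L,
                          beta_nonnull_fraction = 0.1,
                          beta_location = 3 * sqrt(0.5), beta_scale = 0,
                          seed = 42L)
  sim <- simulateDataset(cfg)
  observed <- fitAll(sim$es, alpha = 0.01)
  perm <- runPermutationTest(sim$es, B = 100L, alpha = 0.01, seed = 43L,
                             observed = observed)
  .spiked_cache$run <- list(sim = sim, observed = observed, perm = perm)
  .spiked_cache$run
}
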