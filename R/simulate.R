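#' Simulation configuration for synthetic expression compendia
#'
#' Describes a synthetic compendium with the variance-component structure of
#' the per-probeset crossed mixed-effects model: for probeset p and a sample
#' with disease status i, tissue j and experiment k,
#' \deqn{y = \mu_p + \beta_p 1[i = cancer] + t_j + t_{ij} + e_k + e_{ik} +
#'   \epsilon,}
#' with every random term drawn independently normal with its configured
#' variance, independently per probeset. A sparse subset of probesets carry
#' a nonzero disease effect \eqn{\beta}; its magnitudes are normal around
#' `beta_location` with sd `beta_scale` and a random sign, so effect
#' symmetry (volcano plots) can be checked.
#'
#' @slot n_probesets number of probesets to simulate.
#' @slot tissue_sizes data.frame with columns `tissue`, `n_cancer`,
#'   `n_normal` (one row per tissue).
#' @slot experiments_per_tissue experiments each tissue's samples are spread
#'   over (round-robin, so every experiment mixes both statuses).
#' @slot grand_mean_range range \eqn{\mu_p} is drawn from, log2 units.
#' @slot beta_nonnull_fraction fraction of probesets with \eqn{\beta \ne 0}.
#' @slot beta_location,beta_scale location/scale of nonnull effect
#'   magnitudes (log2 units).
#' @slot var_tissue,var_tissue_disease,var_experiment,var_experiment_disease,var_residual
#'   the five variance components \eqn{\sigma_t^2, \sigma_{t\delta}^2,
#'   \sigma_e^2, \sigma_{e\delta}^2, \sigma^2}.
#' @slot seed integer RNG seed; identical configs give bitwise-identical
#'   output.
#' @seealso [simulationConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
  representation(n_probesets = "integer", tissue_sizes = "data.frame",
                 experiments_per_tissue = "integer",
                 grand_mean_range = "numeric",
                 beta_nonnull_fraction = "numeric",
                 beta_location = "numeric", beta_scale = "numeric",
                 var_tissue = "numeric", var_tissue_disease = "numeric",
                 var_experiment = "numeric",
                 var_experiment_disease = "numeric",
                 var_residual = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  ts <- object@tissue_sizes
  if (!all(c("tissue", "n_cancer", "n_normal") %in% colnames(ts)))
    msg <- c(msg, "tissue_sizes needs columns tissue, n_cancer, n_normal")
  else {
    if (nrow(ts) < 1L) msg <- c(msg, "tissue_sizes is empty")
    if (any(ts$n_cancer < 1L) || any(ts$n_normal < 1L))
      msg <- c(msg, "every tissue needs at least one cancer and one normal sample")
    if (anyDuplicated(ts$tissue)) msg <- c(msg, "duplicate tissue names")
  }
  vc <- c(object@var_tissue, object@var_tissue_disease, object@var_experiment,
          object@var_experiment_disease, object@var_residual)
  if (any(vc < 0)) msg <- c(msg, "variance components must be non-negative")
  # var_residual = 0 is allowed so exact noise-free fixtures can be built
  if (object@beta_nonnull_fraction < 0 || object@beta_nonnull_fraction > 1)
    msg <- c(msg, "beta_nonnull_fraction must lie in [0,1]")
  if (length(object@grand_mean_range) != 2L ||
      diff(object@grand_mean_range) < 0)
    msg <- c(msg, "grand_mean_range must be an increasing length-2 interval")
  if (length(msg)) msg else TRUE
})

#' Paired-tissue sample sizes of the compendium design
#'
#' The 15 paired solid-tissue groups of the real HG-U133Plus2 compendium
#' design, with their cancer/normal sample counts (5,938 samples in total).
#' `scale` shrinks every count (rounding, floor 2) for desk-scale runs.
#'
#' @param scale positive scale factor applied to every group size.
#' @return data.frame with columns `tissue`, `n_cancer`, `n_normal`.
#' @export
defaultTissueSizes <- function(scale = 1) {
  assert_scalar_number(scale, "scale", lower = 1e-6)
  sizes <- data.frame(
    tissue = c("airways and lung", "bone", "brain", "breast", "colon", "fat",
               "gastro-intestinal", "head and neck", "kidney", "mesenchymal",
               "pancreas", "prostate", "skin", "smooth muscle", "uterus"),
    n_cancer = c(309L, 37L, 330L, 926L, 575L, 72L, 293L, 96L, 44L, 129L,
                 73L, 88L, 61L, 73L, 79L),
    n_normal = c(447L, 23L, 474L, 222L, 168L, 448L, 79L, 84L, 269L, 54L,
                 48L, 21L, 148L, 123L, 145L),
    stringsAsFactors = FALSE)
  if (scale != 1) {
    sizes$n_cancer <- pmax(2L, as.integer(round(sizes$n_cancer * scale)))
    sizes$n_normal <- pmax(2L, as.integer(round(sizes$n_normal * scale)))
  }
  sizes
}

#' Build a simulation configuration
#'
#' Defaults mirror the compendium design: the 15 paired tissues of
#' [defaultTissueSizes()], 14 experiments per tissue (so roughly 212
#' experiments overall), and variance components
#' \eqn{\sigma_t^2 = 1, \sigma_{t\delta}^2 = 0.25, \sigma_e^2 = 0.5,
#' \sigma_{e\delta}^2 = 0.1, \sigma^2 = 0.5} — conventions chosen to put
#' tissue identity first, laboratory effects second and measurement noise on
#' the scale of within-group log2 spread seen in practice.
#'
#' @param n_probesets number of probesets.
#' @param tissue_sizes data.frame of per-tissue (cancer, normal) counts.
#' @param experiments_per_tissue experiments per tissue.
#' @param grand_mean_range interval for \eqn{\mu_p}, log2 units.
#' @param beta_nonnull_fraction fraction of nonnull probesets.
#' @param beta_location,beta_scale nonnull effect magnitude distribution.
#' @param var_tissue,var_tissue_disease,var_experiment,var_experiment_disease,var_residual
#'   variance components.
#' @param seed RNG seed.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(n_probesets = 200L,
                             tissue_sizes = defaultTissueSizes(),
                             experiments_per_tissue = 14L,
                             grand_mean_range = c(4, 12),
                             beta_nonnull_fraction = 0.1,
                             beta_location = 1, beta_scale = 0.25,
                             var_tissue = 1, var_tissue_disease = 0.25,
                             var_experiment = 0.5,
                             var_experiment_disease = 0.1,
                             var_residual = 0.5,
                             seed = 1L) {
  new("SimulationConfig",
      n_probesets = assert_count(n_probesets, "n_probesets"),
      tissue_sizes = as.data.frame(tissue_sizes, stringsAsFactors = FALSE),
      experiments_per_tissue = assert_count(experiments_per_tissue,
                                            "experiments_per_tissue"),
      grand_mean_range = as.numeric(grand_mean_range),
      beta_nonnull_fraction = beta_nonnull_fraction,
      beta_location = beta_location, beta_scale = beta_scale,
      var_tissue = var_tissue, var_tissue_disease = var_tissue_disease,
      var_experiment = var_experiment,
      var_experiment_disease = var_experiment_disease,
      var_residual = var_residual,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_probesets, "probesets,",
      nrow(object@tissue_sizes), "tissues,",
      sum(object@tissue_sizes$n_cancer) + sum(object@tissue_sizes$n_normal),
      "samples\n")
  cat(sprintf("  var components (t, td, e, ed, resid): %g %g %g %g %g\n",
              object@var_tissue, object@var_tissue_disease,
              object@var_experiment, object@var_experiment_disease,
              object@var_residual))
  cat(sprintf("  nonnull fraction %g, |beta| ~ N(%g, %g^2), seed %d\n",
              object@beta_nonnull_fraction, object@beta_location,
              object@beta_scale, object@seed))
})

#' Simulate an annotated expression compendium with known truth
#'
#' Generates expression values from the crossed random-effects model (see
#' [SimulationConfig-class]). Samples within a tissue are assigned to that
#' tissue's experiments round-robin across the cancer-then-normal sample
#' sequence, so every experiment contains both disease statuses.
#' Every random term is redrawn independently for every probeset.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements
#'   \item{es}{the simulated [AnnotatedExpressionSet-class];}
#'   \item{truth}{a list with per-probeset `beta`, `mu`, `is_null`, and
#'     `random_effects` — the realized tissue, tissue-by-disease, experiment
#'     and experiment-by-disease draws (matrices, probesets x levels).}
#' @seealso [simulateNull()]
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  ts <- config@tissue_sizes
  P <- config@n_probesets

  tissue <- rep(ts$tissue, ts$n_cancer + ts$n_normal)
  disease <- unlist(lapply(seq_len(nrow(ts)), function(i)
    c(rep("cancer", ts$n_cancer[i]), rep("normal", ts$n_normal[i]))),
    use.names = FALSE)
  experiment <- unlist(lapply(seq_len(nrow(ts)), function(i) {
    n <- ts$n_cancer[i] + ts$n_normal[i]
    sprintf("%s_exp%02d", ts$tissue[i],
            rep_len(seq_len(config@experiments_per_tissue), n))
  }), use.names = FALSE)
  n <- length(tissue)
  sample_ids <- sprintf("sample%05d", seq_len(n))
  probeset_ids <- sprintf("ps%05d_at", seq_len(P))

  tis_f <- factor(tissue, levels = unique(tissue))
  td_f <- factor(paste(tissue, disease, sep = ":"),
                 levels = unique(paste(tissue, disease, sep = ":")))
  exp_f <- factor(experiment, levels = unique(experiment))
  ed_f <- factor(paste(experiment, disease, sep = ":"),
                 levels = unique(paste(experiment, disease, sep = ":")))
  cancer <- as.numeric(disease == "cancer")

  with_seed(config@seed, {
    mu <- runif(P, config@grand_mean_range[1L], config@grand_mean_range[2L])
    n_nonnull <- round(config@beta_nonnull_fraction * P)
    nonnull <- if (n_nonnull > 0) sample.int(P, n_nonnull) else integer()
    beta <- numeric(P)
    if (n_nonnull > 0) {
      mag <- rnorm(n_nonnull, config@beta_location, config@beta_scale)
      sign <- sample(c(-1, 1), n_nonnull, replace = TRUE)
      beta[nonnull] <- sign * mag
    }
    draw <- function(nlev, v, prefix)
      matrix(rnorm(P * nlev, sd = sqrt(v)), P, nlev,
             dimnames = list(probeset_ids, prefix))
    t_j  <- draw(nlevels(tis_f), config@var_tissue, levels(tis_f))
    t_ij <- draw(nlevels(td_f), config@var_tissue_disease, levels(td_f))
    e_k  <- draw(nlevels(exp_f), config@var_experiment, levels(exp_f))
    e_ik <- draw(nlevels(ed_f), config@var_experiment_disease, levels(ed_f))
    eps <- matrix(rnorm(P * n, sd = sqrt(config@var_residual)), P, n)
    values <- mu + outer(beta, cancer) +
      t_j[, as.integer(tis_f), drop = FALSE] +
      t_ij[, as.integer(td_f), drop = FALSE] +
      e_k[, as.integer(exp_f), drop = FALSE] +
      e_ik[, as.integer(ed_f), drop = FALSE] + eps
    dimnames(values) <- list(probeset_ids, sample_ids)
    ann <- data.frame(sample_id = sample_ids,
                      biological_group = paste(tissue, disease, sep = "_"),
                      tissue = tissue, experiment = experiment,
                      disease_status = disease, stringsAsFactors = FALSE)
    list(es = AnnotatedExpressionSet(values, ann),
         truth = list(beta = setNames(beta, probeset_ids),
                      mu = setNames(mu, probeset_ids),
                      is_null = setNames(beta == 0, probeset_ids),
                      random_effects = list(tissue = t_j,
                                            tissue_disease = t_ij,
                                            experiment = e_k,
                                            experiment_disease = e_ik)))
  })
}

#' Simulate a fully null compendium
#'
#' As [simulateDataset()] with the nonnull fraction forced to zero: every
#' probeset has \eqn{\beta = 0}. The calibration harness for type-I error
#' and permutation FDR checks.
#'
#' @inheritParams simulateDataset
#' @return as [simulateDataset()]; `truth$is_null` is all `TRUE`.
#' @export
simulateNull <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  config@beta_nonnull_fraction <- 0
  simulateDataset(config)
}
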