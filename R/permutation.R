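#' PermutationResult: within-tissue permutation inference summary
#'
#' @slot B number of permutations.
#' @slot empirical_p per-probeset empirical p-values (fraction of permuted
#'   statistics at least as extreme as the observed one).
#' @slot empirical_p_adjusted their Benjamini-Hochberg adjustment.
#' @slot F_hat mean number of probesets called significant per permutation
#'   (expected false-positive count under the permutation null).
#' @slot S observed significant count from the unpermuted fit.
#' @slot pi0 estimated proportion of truly null probesets.
#' @slot fdr_estimate the plug-in estimate \eqn{\hat{FDR} = \pi_0 F / S}
#'   (NA when S = 0, where the estimator is undefined).
#' @slot sig_counts per-permutation significant counts (length B).
#' @slot skipped_draws per-probeset number of non-converged permutation
#'   fits excluded from the empirical-p denominator.
#' @slot perm_p_adjusted BH-adjusted model p-values from the first
#'   permutation (the shuffled-label reference for QQ comparison).
#' @slot perm_abs_t B x probesets matrix of permuted |t| statistics (NA for
#'   non-converged draws); the raw material of the empirical p-values.
#' @slot seed RNG seed the run used.
#' @seealso [runPermutationTest()]
#' @export
setClass("PermutationResult",
  representation(B = "integer", empirical_p = "numeric",
                 empirical_p_adjusted = "numeric", F_hat = "numeric",
                 S = "integer", pi0 = "numeric", fdr_estimate = "numeric",
                 sig_counts = "numeric", skipped_draws = "integer",
                 perm_p_adjusted = "numeric", perm_abs_t = "matrix",
                 seed = "integer"))

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: B =", object@B, "\n")
  cat(sprintf("  S = %d, F_hat = %.4g, pi0 = %.4g, FDR estimate = %.6g\n",
              object@S, object@F_hat, object@pi0, object@fdr_estimate))
})

#' Permute disease labels within each tissue
#'
#' Reassigns the disease labels uniformly at random across the samples of
#' each tissue (or, with `scope = "experiment"`, of each experiment — a
#' stricter scheme that also preserves per-study label counts). The
#' multiset of labels within every permutation unit is preserved exactly;
#' tissue and experiment annotations are untouched. Uses the ambient RNG
#' stream (seed at the call site for reproducibility).
#'
#' @param tissue,disease character vectors of per-sample annotations.
#' @param experiment per-sample experiment ids (needed when
#'   `scope = "experiment"`).
#' @param scope permutation unit, `"tissue"` (default) or `"experiment"`.
#' @return the permuted disease label vector.
#' @export
permuteWithinTissue <- function(tissue, disease, experiment = NULL,
                                scope = c("tissue", "experiment")) {
  scope <- match.arg(scope)
  unit <- if (scope == "tissue") tissue else {
    if (is.null(experiment)) stop("'experiment' needed for scope = 'experiment'")
    experiment
  }
  stopifnot(length(unit) == length(disease))
  out <- disease
  for (u in unique(unit)) {
    idx <- which(unit == u)
    out[idx] <- disease[idx][sample.int(length(idx))]
  }
  out
}

#' Estimate the proportion of truly null probesets
#'
#' \eqn{\hat\pi_0 = \#\{p_i > \lambda\} / ((1 - \lambda) m)}, clipped to
#' (0, 1]. When no p-value exceeds \eqn{\lambda} the estimate is floored at
#' \eqn{(1/m)/(1-\lambda)} and the result carries attribute
#' `"floored" = TRUE`.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param lambda tuning parameter in (0, 1); default 0.5.
#' @return the estimate, a scalar in (0, 1].
#' @export
estimatePi0 <- function(p_values, lambda = 0.5) {
  if (!length(p_values)) stop("empty p-value vector")
  if (anyNA(p_values) || min(p_values) < 0 || max(p_values) > 1)
    stop("p-values must lie in [0, 1]")
  assert_scalar_number(lambda, "lambda", lower = 1e-12, upper = 1 - 1e-12)
  m <- length(p_values)
  pi0 <- sum(p_values > lambda) / ((1 - lambda) * m)
  floored <- pi0 == 0
  if (floored) pi0 <- (1 / m) / (1 - lambda)
  pi0 <- min(pi0, 1)
  attr(pi0, "floored") <- floored
  pi0
}

#' Plug-in permutation FDR estimate
#'
#' \eqn{\hat{FDR} = \pi_0 F / S}: the estimated null proportion times the
#' permutation-expected false-positive count, over the observed significant
#' count.
#'
#' @param pi0 estimated null proportion (see [estimatePi0()]).
#' @param F_hat mean significant count across permutations.
#' @param S observed significant count; must be positive (the estimator is
#'   undefined at S = 0).
#' @return the FDR estimate.
#' @examples
#' pluginFdr(1, 0.0019, 1835)
#' @export
pluginFdr <- function(pi0, F_hat, S) {
  assert_scalar_number(pi0, "pi0", lower = 0, upper = 1)
  assert_scalar_number(F_hat, "F_hat", lower = 0)
  if (!is.numeric(S) || length(S) != 1L || is.na(S) || S <= 0)
    stop("S must be a positive count; the plug-in estimator is undefined at S = 0")
  as.numeric(pi0) * F_hat / S
}

#' Within-tissue permutation test of the disease effect
#'
#' Runs the full permutation machinery around [fitAll()]: for each of `B`
#' within-tissue label permutations the model is refitted to every
#' probeset; empirical p-values are the fraction of permuted \eqn{|t|}
#' statistics at least as extreme as the observed one (ties count as
#' extreme; two-sided by construction). Per permutation, the
#' fit-test-adjust pipeline is also run at level `alpha` and the
#' significant probesets counted, giving the expected false-positive count
#' \eqn{F}. Together with the observed significant count \eqn{S} and
#' \eqn{\hat\pi_0} from the observed model p-values this yields the plug-in
#' estimate \eqn{\hat{FDR} = \pi_0 F / S}.
#'
#' Non-converged permutation fits are skipped for the affected probeset
#' (denominator reduced) and counted in `skipped_draws`.
#'
#' @param es a paired-tissue [AnnotatedExpressionSet-class].
#' @param B number of permutations.
#' @param alpha significance level for the per-permutation BH calls.
#' @param seed RNG seed; identical seeds give identical results.
#' @param lambda \eqn{\pi_0} tuning parameter (default 0.5).
#' @param scope permutation unit passed to [permuteWithinTissue()].
#' @param pseudo_count if `TRUE`, empirical p-values use the
#'   \eqn{(\#+1)/(B+1)} correction instead of the plain fraction
#'   \eqn{\#/B}; off by default, so an observed statistic exceeding every
#'   permuted one yields p = 0.
#' @param observed optionally, a precomputed [SignificanceTable-class] for
#'   `es` at this `alpha` (avoids refitting the observed data).
#' @return a [PermutationResult-class].
#' @export
runPermutationTest <- function(es, B = 200L, alpha = 0.01, seed = 1L,
                               lambda = 0.5,
                               scope = c("tissue", "experiment"),
                               pseudo_count = FALSE, observed = NULL) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  B <- assert_count(B, "B")
  scope <- match.arg(scope)
  if (is.null(observed)) observed <- fitAll(es, alpha = alpha)
  obs <- observed@table
  P <- nrow(obs)
  t_obs <- abs(obs$t_stat)
  tissue <- tissueType(es)
  experiment <- experimentId(es)
  disease <- diseaseStatus(es)
  Y <- exprValues(es)

  count_ge <- integer(P)
  denom <- integer(P)
  skipped <- integer(P)
  sig_counts <- numeric(B)
  perm_p_adj_first <- rep(NA_real_, P)
  perm_abs_t <- matrix(NA_real_, B, P, dimnames = list(NULL, obs$probeset_id))
  with_seed(seed, {
    for (b in seq_len(B)) {
      dperm <- permuteWithinTissue(tissue, disease, experiment, scope)
      design <- .prepDesign(tissue, experiment, dperm)
      res <- .fitMatrix(design, Y, reltol = 1e-8)
      conv <- res$converged
      tb <- abs(res$stats[, "t"])
      perm_abs_t[b, conv] <- tb[conv]
      ok <- conv & !is.na(t_obs)
      count_ge[ok] <- count_ge[ok] + (tb[ok] >= t_obs[ok])
      denom[ok] <- denom[ok] + 1L
      skipped <- skipped + as.integer(!conv)
      padj <- rep(NA_real_, P)
      padj[conv] <- bhAdjust(res$stats[conv, "p"])
      sig_counts[b] <- sum(padj < alpha, na.rm = TRUE)
      if (b == 1L) perm_p_adj_first <- padj
    }
  })
  emp_p <- rep(NA_real_, P)
  has <- denom > 0L
  emp_p[has] <- if (pseudo_count) (count_ge[has] + 1) / (denom[has] + 1)
                else count_ge[has] / denom[has]
  emp_adj <- rep(NA_real_, P)
  emp_adj[!is.na(emp_p)] <- bhAdjust(emp_p[!is.na(emp_p)])
  S <- sum(obs$significant, na.rm = TRUE)
  pi0 <- estimatePi0(obs$p_value[obs$converged], lambda = lambda)
  fdr <- if (S > 0) pluginFdr(as.numeric(pi0), mean(sig_counts), S)
         else NA_real_
  new("PermutationResult", B = B, empirical_p = setNames(emp_p, obs$probeset_id),
      empirical_p_adjusted = setNames(emp_adj, obs$probeset_id),
      F_hat = mean(sig_counts), S = as.integer(S), pi0 = as.numeric(pi0),
      fdr_estimate = fdr, sig_counts = sig_counts,
      skipped_draws = setNames(skipped, obs$probeset_id),
      perm_p_adjusted = setNames(perm_p_adj_first, obs$probeset_id),
      perm_abs_t = perm_abs_t, seed = as.integer(seed))
}

#' Empirical permutation p-values
#'
#' Convenience wrapper around [runPermutationTest()] returning only the
#' per-probeset empirical p-values (fraction of permuted statistics at
#' least as extreme as the observed one) and their BH adjustment.
#'
#' @inheritParams runPermutationTest
#' @return a [PermutationResult-class] (see its `empirical_p` slot).
#' @export
permutationPvalues <- function(es, B, seed = 1L, ...) {
  runPermutationTest(es, B = B, seed = seed, ...)
}

#' Permutation-expected false-positive count
#'
#' Runs the fit-test-adjust pipeline at level `alpha` on each of `B`
#' permuted labellings and averages the significant counts.
#'
#' @inheritParams runPermutationTest
#' @return scalar \eqn{\hat F}.
#' @export
expectedFalsePositives <- function(es, B, alpha = 0.01, seed = 1L, ...) {
  runPermutationTest(es, B = B, alpha = alpha, seed = seed, ...)@F_hat
}

#' QQ export of observed versus permuted adjusted p-values
#'
#' Pairs the sorted \eqn{-\log_{10}} adjusted p-values of the observed fit
#' with those of a permuted (shuffled-label) fit at matching quantiles.
#' Under genuine signal the observed column dominates the permuted one.
#'
#' @param observed_adj,permuted_adj numeric vectors of adjusted p-values
#'   (NAs dropped).
#' @param path optional TSV output path.
#' @return data.frame with ascending columns `observed` and `permuted`
#'   (\eqn{-\log_{10}} scale).
#' @export
qqExport <- function(observed_adj, permuted_adj, path = NULL) {
  o <- sort(-log10(pmax(observed_adj[!is.na(observed_adj)], 1e-300)))
  p <- sort(-log10(pmax(permuted_adj[!is.na(permuted_adj)], 1e-300)))
  if (!length(o) || !length(p)) stop("need non-empty p-value vectors")
  n <- min(length(o), length(p))
  probs <- ppoints(n)
  df <- data.frame(observed = quantile(o, probs, names = FALSE, type = 7),
                   permuted = quantile(p, probs, names = FALSE, type = 7))
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
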